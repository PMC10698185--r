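#' Agricultural land-cover classes
#'
#' The six agricultural land-cover classes within which active-substance use
#' is modelled independently: arable land, fruit tree, grassland, olive
#' groves, vineyards and rice fields.
#'
#' @return Character vector of the six class names.
#' @export
landcover_classes <- function() {
  c("arable land", "fruit tree", "grassland", "olive groves",
    "vineyards", "rice fields")
}

#' Default crop inventory: 44 crop codes in 16 model groups
#'
#' A synthetic stand-in for the EUROSTAT annual-crop-statistics code list:
#' 44 crop codes rolling up into the 16 crop groups used as area predictors,
#' each group tied to one of the six land-cover classes.  The group ids and
#' the group-to-class assignment follow the standard modelling inventory
#' (cereal grain C0000, plants harvested green G0000, industrial crops
#' I0000, dry pulses P0000, fallow Q0000, root crops R0000, fresh
#' vegetables/strawberries V_S0000, seeds E0000, nurseries L0000, other
#' arable OTHER_ARA, fruits/berries/nuts F0000, citrus T0000, permanent
#' grassland J0000, olives O1000, grapes W1000, rice C2000); the member
#' subcodes are synthetic.
#'
#' @return Data frame with columns `crop_code`, `crop_group`, `landcover`.
#' @export
default_crop_inventory <- function() {
  g <- function(group, class, codes) {
    data.frame(crop_code = codes, crop_group = group, landcover = class,
               stringsAsFactors = FALSE)
  }
  inv <- rbind(
    g("C0000", "arable land",
      c("C1100", "C1200", "C1300", "C1400", "C1500", "C1600", "C1700", "C1900")),
    g("G0000", "arable land", c("G1000", "G2000", "G3000")),
    g("I0000", "arable land", c("I1100", "I2000", "I3000", "I4000")),
    g("P0000", "arable land", c("P1100", "P1200", "P9000")),
    g("Q0000", "arable land", "Q0000"),
    g("R0000", "arable land", c("R1000", "R2000", "R9000")),
    g("V_S0000", "arable land", c("V1000", "S0000", "V9000")),
    g("E0000", "arable land", "E0000"),
    g("L0000", "arable land", "L0000"),
    g("OTHER_ARA", "arable land", c("N0000", "K0000", "OTHER_ARA")),
    g("F0000", "fruit tree", c("F1000", "F2000", "F3000", "F4000")),
    g("T0000", "fruit tree", c("T1000", "T2000")),
    g("J0000", "grassland", c("J1000", "J2000", "J3000")),
    g("O1000", "olive groves", "O1000"),
    g("W1000", "vineyards", c("W1000", "W1100", "W1200")),
    g("C2000", "rice fields", "C2000")
  )
  rownames(inv) <- NULL
  inv
}

#' Crop-group to land-cover class map
#'
#' @param inventory A crop inventory as returned by
#'   [default_crop_inventory()].
#' @return Named character vector mapping crop-group id to land-cover class.
#' @export
group_landcover_map <- function(inventory = default_crop_inventory()) {
  u <- unique(inventory[, c("crop_group", "landcover")])
  stats::setNames(u$landcover, u$crop_group)
}

#' Crop-code to crop-group map
#'
#' @inheritParams group_landcover_map
#' @return Named character vector mapping crop code to crop-group id.
#' @export
crop_group_map <- function(inventory = default_crop_inventory()) {
  if (anyDuplicated(inventory$crop_code) > 0) {
    stop("crop inventory maps a code to more than one group: ",
         paste(unique(inventory$crop_code[duplicated(inventory$crop_code)]),
               collapse = ", "), call. = FALSE)
  }
  stats::setNames(inventory$crop_group, inventory$crop_code)
}
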