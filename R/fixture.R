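#' Reference synthetic study: landscape, substances, truth and reporting
#'
#' Builds the default end-to-end synthetic study used throughout the
#' package: 12 countries (8 reporting, 4 not) of 10 regions each over the
#' full 44-code crop inventory (16 crop groups across all six land-cover
#' classes), a catalog of 12 active substances with known doses, a mixed
#' reporting scheme (country-, province- and region-level reporters, like
#' real national sources), climate cell samples, and the resulting true
#' use.  Ground-truth doses double as the catalog's recommended dose
#' weights, the way manufacturer references drive apportionment in the
#' real pipeline.
#'
#' @param seed Integer seed (default 42).
#' @param noise_sd Log-scale sd of multiplicative noise on true use.
#' @param coverage_fraction Reported-coverage fraction of total areas.
#' @param regions_per_country Regions per country (default 10).
#' @param climate_coefs Optional climate coefficient table passed to
#'   [synthetic_truth()].
#' @param unreported_crops Optional named list of crop codes omitted by a
#'   country's reports.
#' @return List with elements `regions`, `climate_cells`, `inventory`,
#'   `truth`, `catalog`, `doses`, `scheme`, `authorizations`, `true_use`,
#'   `reported`, `reporting_countries`.
#' @export
reference_fixture <- function(seed = 42L, noise_sd = 0,
                              coverage_fraction = 1,
                              regions_per_country = 10L,
                              climate_coefs = NULL,
                              unreported_crops = list()) {
  inventory <- default_crop_inventory()
  regions <- generate_landscape(
    n_countries = 12L, regions_per_country = regions_per_country,
    crop_codes = inventory$crop_code, seed = seed,
    coverage_fraction = coverage_fraction)
  climate_cells <- generate_climate(regions, cells_per_region = 5L,
                                    seed = seed + 1L)
  catalog <- reference_catalog()
  doses <- reference_doses()
  truth <- synthetic_truth(doses, climate_coefs = climate_coefs,
                           noise_sd = noise_sd, seed = seed + 2L)
  climate_features <- if (!is.null(climate_coefs)) {
    summarize_climate(climate_cells)
  } else NULL
  true_use <- simulate_true_use(truth, regions,
                                crop_grouping = crop_group_map(inventory),
                                climate_features = climate_features,
                                inventory = inventory)
  reporting <- sprintf("CN%02d", 1:8)
  scheme <- reporting_scheme(
    resolution = stats::setNames(
      c("country", "country", "country", "country",
        "province", "province", "region", "region"), reporting),
    unreported_crops = unreported_crops,
    non_reporting = character())
  reported <- simulate_reporting(true_use, scheme, regions)
  auth <- expand.grid(country = sprintf("CN%02d", 1:12),
                      substance_id = catalog$substance_id,
                      stringsAsFactors = FALSE)
  auth$authorized <- TRUE
  list(regions = regions, climate_cells = climate_cells,
       inventory = inventory, truth = truth, catalog = catalog,
       doses = doses, scheme = scheme, authorizations = auth,
       true_use = true_use, reported = reported,
       reporting_countries = reporting)
}

#' Reference substance catalog (synthetic)
#'
#' Twelve synthetic active substances spanning the six categories and all
#' six land-cover classes; identifiers (CAS, CIPAC, EU pesticide database
#' id) are synthetic placeholders in the published schema's format.
#'
#' @return Data frame with columns `substance_id`, `common_name`,
#'   `category`, `chemical_class`, `CAS`, `CIPAC`, `ID_EUPDB`.
#' @export
reference_catalog <- function() {
  data.frame(
    substance_id = sprintf("S%02d", 1:12),
    common_name = c("glyphosar", "pendimetron", "mancozan", "folpetin",
                    "deltametrix", "mcpazol", "copperol", "quinclomet",
                    "lambdacyn", "chlormequol", "metaldehin", "sulfurix"),
    category = c("Herbicide", "Herbicide", "Fungicide", "Fungicide",
                 "Insecticide", "Herbicide", "Fungicide", "Herbicide",
                 "Insecticide", "Plant growth regulator", "Molluscicide",
                 "Other"),
    chemical_class = c("Phosphonoglycines", "Dinitroanilines",
                       "Dithiocarbamates", "Phthalimides", "Pyrethroids",
                       "Phenoxy-phytohormones", "Inorganics",
                       "Quinolinecarboxylic acids", "Pyrethroids",
                       "Quaternary ammoniums", "Aldehydes", "Inorganics"),
    CAS = sprintf("%04d-%02d-%d", 1000 + 17 * (1:12), (1:12) * 3 %% 90 + 1,
                  (1:12) %% 10),
    CIPAC = 100 + 7 * (1:12),
    ID_EUPDB = sprintf("EUPDB-%03d", 200 + (1:12)),
    stringsAsFactors = FALSE)
}

#' Reference ground-truth doses (synthetic)
#'
#' Dose (kg/ha) per substance and crop group.  Substances cover the whole
#' range of applicability patterns: broad arable-land herbicides,
#' single-class specialists (vineyards, grassland, olive groves, rice),
#' and multi-class products whose regional mass must be split across
#' classes.
#'
#' @return Data frame with columns `substance_id`, `crop_group`, `dose`.
#' @export
reference_doses <- function() {
  d <- function(s, g, dose) data.frame(substance_id = s, crop_group = g,
                                       dose = dose, stringsAsFactors = FALSE)
  out <- rbind(
    d("S01", c("C0000", "G0000", "I0000", "P0000", "R0000"),
      c(1.5, 0.8, 1.2, 0.6, 1.0)),
    d("S02", c("C0000", "Q0000", "V_S0000"), c(0.9, 0.4, 1.1)),
    d("S03", c("F0000", "W1000"), c(2.5, 3.0)),
    d("S04", "W1000", 1.8),
    d("S05", c("F0000", "T0000"), c(0.05, 0.08)),
    d("S06", "J0000", 0.7),
    d("S07", "O1000", 4.0),
    d("S08", "C2000", 1.3),
    d("S09", c("C0000", "V_S0000"), c(0.12, 0.30)),
    d("S10", c("C0000", "E0000"), c(0.6, 0.5)),
    d("S11", c("V_S0000", "R0000"), c(0.25, 0.15)),
    d("S12", c("C0000", "F0000", "W1000", "O1000"),
      c(0.8, 1.6, 2.0, 2.2))
  )
  rownames(out) <- NULL
  out
}

#' Substance profiles from a catalog and dose table
#'
#' Joins identity, applicability and dose-weight information into one list
#' of per-substance profiles, the unit the disaggregation and modelling
#' stages work with.
#'
#' @param catalog Substance catalog (see [reference_catalog()]).
#' @param doses Dose table (`substance_id`, `crop_group`, `dose`).
#' @param inventory Crop inventory mapping codes to groups and classes.
#' @return Named list of `substance_profile` objects, each a list with the
#'   catalog fields plus `dose_weights` (named by crop group),
#'   `applicable_groups`, `applicable_codes`, `landcovers`.
#' @export
substance_profiles <- function(catalog, doses,
                               inventory = default_crop_inventory()) {
  check_columns(catalog, c("substance_id", "common_name", "category",
                           "chemical_class", "CAS", "CIPAC", "ID_EUPDB"),
                "`catalog`")
  check_columns(doses, c("substance_id", "crop_group", "dose"), "`doses`")
  class_map <- group_landcover_map(inventory)
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    d <- doses[doses$substance_id == row$substance_id & doses$dose > 0, ]
    check_that(nrow(d) >= 1, "substance ", row$substance_id,
               " has no applicable crop group with positive dose")
    weights <- stats::setNames(d$dose, d$crop_group)
    codes <- inventory$crop_code[inventory$crop_group %in% d$crop_group]
    structure(c(as.list(row),
                list(dose_weights = weights,
                     applicable_groups = d$crop_group,
                     applicable_codes = codes,
                     landcovers = unique(unname(class_map[d$crop_group])))),
              class = "substance_profile")
  })
  stats::setNames(out, catalog$substance_id)
}
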