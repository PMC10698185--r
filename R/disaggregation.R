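#' Dose-weighted applicable hectares of a substance per region
#'
#' The apportionment weight of a region for one substance: the sum over the
#' substance's applicable crops of the crop area times the relative dose
#' weight of its crop group.  With uniform dose weights this reduces to the
#' plain applicable area.
#'
#' @param regions Landscape table (all rows are scored).
#' @param profile A `substance_profile` (see [substance_profiles()]).
#' @param variant `"reported"` (calibration extents, the default here) or
#'   `"total"` (prediction extents).
#' @param inventory Crop inventory mapping codes to groups.
#' @return Named numeric vector of weighted hectares, one per region.
#' @export
applicable_weight <- function(regions, profile,
                              variant = c("reported", "total"),
                              inventory = default_crop_inventory()) {
  variant <- match.arg(variant)
  areas <- region_areas(regions, variant)
  grouping <- crop_group_map(inventory)
  codes <- intersect(profile$applicable_codes, colnames(areas))
  if (length(codes) == 0) {
    return(stats::setNames(rep(0, nrow(areas)), rownames(areas)))
  }
  w <- profile$dose_weights[grouping[codes]]
  out <- as.numeric(areas[, codes, drop = FALSE] %*% w)
  stats::setNames(out, rownames(areas))
}

# Resolve a report's scope to the region ids it covers.
resolve_scope <- function(scope, regions) {
  if (scope %in% regions$country) {
    regions$region_id[regions$country == scope]
  } else if (scope %in% regions$province) {
    regions$region_id[regions$province == scope]
  } else if (scope %in% regions$region_id) {
    scope
  } else {
    character()
  }
}

#' Disaggregate one reported amount to the regions in its scope
#'
#' Splits a reported amount across the regions its scope covers,
#' proportionally to the regions' dose-weighted applicable crop areas.
#' Mass is conserved exactly.  If every region in scope has zero weight,
#' the amount is spread uniformly and a warning is emitted (the record is
#' kept rather than lost).
#'
#' @param report One reported-use record (list or one-row data frame with
#'   `scope`, `substance_id`, `kg`).
#' @param regions Landscape table.
#' @param profile The substance's profile.
#' @param variant Area variant used for the weights (calibration uses
#'   `"reported"`).
#' @param inventory Crop inventory.
#' @return Data frame `region_id`, `country`, `substance_id`, `kg`
#'   (class-agnostic), one row per region in scope.
#' @export
disaggregate_report <- function(report, regions,
                                profile,
                                variant = c("reported", "total"),
                                inventory = default_crop_inventory()) {
  variant <- match.arg(variant)
  ids <- resolve_scope(report$scope, regions)
  check_that(length(ids) >= 1, "scope '", report$scope,
             "' resolves to no region")
  sub <- regions[match(ids, regions$region_id), , drop = FALSE]
  w <- applicable_weight(sub, profile, variant, inventory)
  if (sum(w) <= 0) {
    warning("all-zero applicable weights for substance ",
            report$substance_id, " in scope '", report$scope,
            "'; spreading uniformly", call. = FALSE)
    w[] <- 1
  }
  data.frame(region_id = ids, country = sub$country,
             substance_id = report$substance_id,
             kg = report$kg * w / sum(w),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Disaggregate a full reported-use table to regions
#'
#' @param reported Reported-use data frame (`country`, `scope`,
#'   `substance_id`, `kg`).
#' @param regions Landscape table.
#' @param profiles Named list of substance profiles.
#' @param variant Area variant for the weights.
#' @param inventory Crop inventory.
#' @return Data frame `region_id`, `country`, `substance_id`, `kg`.
#' @export
disaggregate_all <- function(reported, regions, profiles,
                             variant = c("reported", "total"),
                             inventory = default_crop_inventory()) {
  variant <- match.arg(variant)
  parts <- lapply(seq_len(nrow(reported)), function(i) {
    r <- reported[i, ]
    disaggregate_report(r, regions, profiles[[r$substance_id]], variant,
                        inventory)
  })
  out <- do.call(rbind, parts)
  agg <- stats::aggregate(
    out["kg"], by = out[, c("region_id", "country", "substance_id")],
    FUN = sum)
  agg <- agg[order(agg$substance_id, agg$region_id), ]
  rownames(agg) <- NULL
  agg
}

#' Split a substance's regional amount across land-cover classes
#'
#' A substance used in more than one land-cover class is distributed among
#' the classes it applies to, proportionally to the recommended-dose-
#' weighted applicable area of each class in the region.  Shares sum to 1;
#' a single-class substance maps 100% to its class; classes with zero
#' applicable area in a region receive 0.
#'
#' @param regional_use Data frame `region_id`, `country`, `substance_id`,
#'   `kg` (class-agnostic).
#' @param profile The substance's profile.
#' @param regions Landscape table.
#' @param variant Area variant used for the class shares.
#' @param inventory Crop inventory.
#' @return Data frame `region_id`, `country`, `substance_id`, `landcover`,
#'   `kg`, one row per (region, applicable class).
#' @export
split_by_landcover <- function(regional_use, profile, regions,
                               variant = c("reported", "total"),
                               inventory = default_crop_inventory()) {
  variant <- match.arg(variant)
  areas <- region_areas(regions, variant)
  grouping <- crop_group_map(inventory)
  class_map <- group_landcover_map(inventory)
  classes <- profile$landcovers
  idx <- match(regional_use$region_id, rownames(areas))
  # per-class dose-weighted applicable area for every row's region
  share <- matrix(0, nrow = nrow(regional_use), ncol = length(classes),
                  dimnames = list(NULL, classes))
  for (cl in classes) {
    groups <- profile$applicable_groups[
      class_map[profile$applicable_groups] == cl]
    codes <- intersect(inventory$crop_code[inventory$crop_group %in% groups],
                       colnames(areas))
    if (length(codes) == 0) next
    w <- profile$dose_weights[grouping[codes]]
    share[, cl] <- as.numeric(areas[idx, codes, drop = FALSE] %*% w)
  }
  tot <- rowSums(share)
  # regions with no applicable area at all: put everything in the first
  # applicable class (kg there is typically 0 already)
  share[tot == 0, 1] <- 1
  share <- share / rowSums(share)
  out <- do.call(rbind, lapply(seq_along(classes), function(j) {
    data.frame(region_id = regional_use$region_id,
               country = regional_use$country,
               substance_id = regional_use$substance_id,
               landcover = classes[j],
               kg = regional_use$kg * share[, j],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$substance_id, out$region_id, out$landcover), ]
  rownames(out) <- NULL
  out
}

#' Disaggregate and class-split a reported table in one call
#'
#' Produces the calibration table consumed by the feature and modelling
#' stages: one row per (region, substance, land-cover class) with its kg.
#'
#' @inheritParams disaggregate_all
#' @return Data frame `region_id`, `country`, `substance_id`, `landcover`,
#'   `kg`.
#' @export
build_calibration_table <- function(reported, regions, profiles,
                                    variant = c("reported", "total"),
                                    inventory = default_crop_inventory()) {
  variant <- match.arg(variant)
  regional <- disaggregate_all(reported, regions, profiles, variant,
                               inventory)
  parts <- lapply(split(regional, regional$substance_id), function(ru) {
    split_by_landcover(ru, profiles[[ru$substance_id[1]]], regions, variant,
                       inventory)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
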