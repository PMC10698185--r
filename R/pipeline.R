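# End-to-end drivers tying the modules together: calibration of the
# cascade over all substance x class datasets, and extrapolation of the
# selected models to every region.

#' Share of each substance within its product category
#'
#' Computes, from the reported amounts, each substance's share by weight
#' of its category's total, and flags the commonly used ones (share above
#' 1%).  The flag is informational context for the audit table -- outlier
#' frequency is empirically higher for these substances -- and never
#' alters the decision policy.
#'
#' @param reported Reported-use table (`substance_id`, `kg`).
#' @param catalog Substance catalog (supplies the category).
#' @param major_threshold Share above which a substance counts as
#'   commonly used (default 0.01).
#' @return Data frame `substance_id`, `category`, `kg`, `share`, `major`.
#' @export
category_weight_shares <- function(reported, catalog,
                                   major_threshold = 0.01) {
  tot <- stats::aggregate(kg ~ substance_id, reported, sum)
  tot$category <- catalog$category[match(tot$substance_id,
                                         catalog$substance_id)]
  cat_tot <- tapply(tot$kg, tot$category, sum)
  tot$share <- tot$kg / as.numeric(cat_tot[tot$category])
  tot$major <- tot$share > major_threshold
  tot[, c("substance_id", "category", "kg", "share", "major")]
}

#' Calibrate the cascade for every eligible substance x class
#'
#' Runs the full calibration side of the pipeline: eligibility filtering,
#' design assembly per substance and land-cover class (over reported-
#' coverage extents and the regions of reporting countries), and the
#' model cascade with its decision policy.
#'
#' @param reported Harmonized reported-use table (`country`, `scope`,
#'   `substance_id`, `kg`).
#' @param regions Landscape table.
#' @param profiles Named list of substance profiles.
#' @param climate_features Regional climate features
#'   ([summarize_climate()]).
#' @param retained_climate Climate features kept by [prune_correlated()].
#' @param policy A [cascade_policy()].
#' @param inventory Crop inventory.
#' @return List with `decisions` (named `cascade_decision` list, one per
#'   substance x applicable class), `audit` (one data-frame row per
#'   decision with its reason code), `eligible` (substance ids), and
#'   `calibration` (the disaggregated calibration table).
#' @export
calibrate_cascade <- function(reported, regions, profiles,
                              climate_features = NULL,
                              retained_climate = character(),
                              policy = cascade_policy(),
                              inventory = default_crop_inventory()) {
  eligible <- eligibility_filter(reported,
                                 substances = names(profiles),
                                 min_countries = policy$min_countries)
  reporting_countries <- unique(reported$country)
  calibration <- build_calibration_table(
    reported[reported$substance_id %in% eligible, , drop = FALSE],
    regions, profiles, variant = "reported", inventory = inventory)
  decisions <- list()
  for (s in eligible) {
    profile <- profiles[[s]]
    for (lcc in profile$landcovers) {
      design <- assemble_design(
        calibration, s, lcc, regions, profile,
        climate_features = climate_features,
        retained_climate = retained_climate,
        reporting_countries = reporting_countries,
        variant = "reported", inventory = inventory)
      decisions[[paste(s, lcc, sep = "|")]] <-
        run_cascade(design, policy)
    }
  }
  shares <- category_weight_shares(
    reported,
    data.frame(substance_id = names(profiles),
               category = vapply(profiles, `[[`, "", "category")))
  audit <- do.call(rbind, lapply(decisions, function(d) {
    data.frame(substance_id = d$substance_id, landcover = d$landcover,
               model_id = d$model_id, reason = d$reason,
               country_specific = isTRUE(d$country_specific),
               cv_nse = d$cv_nse, n_outliers = length(d$outliers),
               major_in_category = shares$major[
                 match(d$substance_id, shares$substance_id)],
               stringsAsFactors = FALSE)
  }))
  rownames(audit) <- NULL
  list(decisions = decisions, audit = audit, eligible = eligible,
       calibration = calibration, shares = shares)
}

#' Extrapolate all selected models and assemble the emission dataset
#'
#' Applies every non-excluded final model to the total-extent predictor
#' table over all regions, masks non-authorized (country, substance)
#' pairs, and assembles the published and detailed emission tables.
#'
#' @param decisions Decision list from [calibrate_cascade()].
#' @param regions Landscape table (all countries, reporting or not).
#' @param climate_features Regional climate features.
#' @param auth Authorization table.
#' @param catalog Substance catalog.
#' @param inventory Crop inventory.
#' @return List with `per_class` (region x substance x class kg after
#'   masking), `primary` and `detailed` emission tables, and counters
#'   `clipped` and `masked`.
#' @export
predict_emissions <- function(decisions, regions, climate_features = NULL,
                              auth = NULL, catalog,
                              inventory = default_crop_inventory()) {
  ptab <- build_prediction_table(regions, climate_features, inventory)
  parts <- list()
  clipped <- 0L
  for (d in decisions) {
    if (identical(d$model_id, "excluded")) next
    est <- extrapolate(d$model, ptab, inventory)
    clipped <- clipped + attr(est, "clipped")
    est$substance_id <- d$substance_id
    est$landcover <- d$landcover
    parts[[length(parts) + 1L]] <- est
  }
  check_that(length(parts) > 0, "no extrapolable model in `decisions`")
  per_class <- do.call(rbind, parts)
  per_class <- per_class[, c("region_id", "country", "substance_id",
                             "landcover", "kg")]
  masked <- 0L
  if (!is.null(auth)) {
    per_class <- apply_authorization(per_class, auth)
    masked <- attr(per_class, "masked")
  }
  ds <- assemble_dataset(per_class, catalog)
  list(per_class = per_class, primary = ds$primary,
       detailed = ds$detailed, clipped = clipped, masked = masked)
}
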