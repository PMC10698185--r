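#' Five-statistic regional climate summaries
#'
#' Reduces per-region climate cell samples to regional features: for each
#' climate variable and region, the minimum, maximum, median, mean and
#' sample (n-1) standard deviation over the region's cells.  With the
#' 24-monthly-variable inventory this yields 120 candidate features.
#'
#' @param cells Long data frame from [generate_climate()] (or equivalent):
#'   `region_id`, `variable`, `value` (a `cell` column is ignored).
#' @return Wide data frame: `region_id` plus one `<variable>_<stat>` column
#'   per variable and statistic.
#' @export
summarize_climate <- function(cells) {
  check_columns(cells, c("region_id", "variable", "value"), "`cells`")
  check_that(nrow(cells) > 0, "no climate cells: every region needs >= 1")
  stats_list <- list(min = min, max = max, median = stats::median,
                     mean = mean, sd = stats::sd)
  vars <- sort(unique(cells$variable))
  regions <- unique(cells$region_id)
  out <- data.frame(region_id = regions, stringsAsFactors = FALSE)
  for (v in vars) {
    sub <- cells[cells$variable == v, ]
    grp <- split(sub$value, factor(sub$region_id, levels = regions))
    lens <- lengths(grp)
    check_that(all(lens >= 1), "region(s) with zero cells for variable ",
               v, ": ", paste(regions[lens == 0], collapse = ", "))
    for (s in names(stats_list)) {
      vals <- vapply(grp, stats_list[[s]], numeric(1))
      # single-cell regions: location statistics are the cell, spread is 0
      if (s == "sd") vals[lens == 1] <- 0
      out[[paste(v, s, sep = "_")]] <- unname(vals)
    }
  }
  out
}

#' Iterative pairwise-correlation pruning of features
#'
#' Removes collinear features: while any pair of retained features has
#' |Pearson r| above the threshold, the currently worst offending pair is
#' located and the member with the larger mean absolute correlation to all
#' remaining features is dropped (the one contributing more to overall
#' collinearity, hence less distinct information).  Ties drop the later
#' column, so the result is deterministic given column order.  Constant
#' columns, whose correlation is undefined, are dropped first with a
#' warning.
#'
#' @param features Data frame (an optional `region_id` column is ignored)
#'   or numeric matrix of candidate features.
#' @param threshold Absolute-correlation cutoff in (0, 1); default 0.9.
#' @return Character vector of retained feature names (in original order).
#' @export
prune_correlated <- function(features, threshold = 0.9) {
  check_that(threshold > 0 && threshold < 1,
             "`threshold` must be in (0, 1)")
  x <- as.data.frame(features)
  x$region_id <- NULL
  check_that(nrow(x) >= 2, "need >= 2 rows to compute correlations")
  x <- as.matrix(x)
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("dropping constant feature(s) (correlation undefined): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  keep <- colnames(x)
  if (length(keep) < 2) return(keep)
  cmat <- abs(stats::cor(x))
  diag(cmat) <- 0
  repeat {
    worst <- max(cmat)
    if (worst <= threshold) break
    pair <- which(cmat == worst, arr.ind = TRUE)[1, ]
    i <- pair[["row"]]; j <- pair[["col"]]
    mi <- mean(cmat[i, -i]); mj <- mean(cmat[j, -j])
    # larger mean |r| goes; on a tie the later column goes
    drop_idx <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    keep <- keep[-drop_idx]
    cmat <- cmat[-drop_idx, -drop_idx, drop = FALSE]
    if (length(keep) < 2) break
  }
  keep
}

#' Group crop-code areas into model predictor columns
#'
#' Sums per-code areas into per-group areas under a code-to-group map;
#' codes absent from the map are dropped (and reported via a message).
#' With the default 44-code inventory this produces the 16 crop-group
#' predictors.
#'
#' @param regions Landscape table.
#' @param grouping Named vector mapping crop code to group id (see
#'   [crop_group_map()]); building it fails if a code maps to two groups.
#' @param variant Area variant to group (`"reported"` or `"total"`).
#' @return Data frame: `region_id` plus one area column per crop group
#'   (ha).
#' @export
group_crops <- function(regions, grouping = crop_group_map(),
                        variant = c("reported", "total")) {
  variant <- match.arg(variant)
  areas <- region_areas(regions, variant)
  codes <- colnames(areas)
  unmapped <- setdiff(codes, names(grouping))
  if (length(unmapped) > 0) {
    message("dropping ", length(unmapped), " crop code(s) outside the ",
            "grouping: ", paste(unmapped, collapse = ", "))
    areas <- areas[, setdiff(codes, unmapped), drop = FALSE]
  }
  groups <- unique(unname(grouping[colnames(areas)]))
  out <- data.frame(region_id = rownames(areas), stringsAsFactors = FALSE)
  for (g in groups) {
    member <- colnames(areas)[grouping[colnames(areas)] == g]
    out[[g]] <- rowSums(areas[, member, drop = FALSE])
  }
  out
}

#' Assemble the design matrix for one substance x land-cover class
#'
#' Joins the calibration response (disaggregated kg of one substance in
#' one class) with its predictors -- the substance's applicable crop-group
#' areas plus the retained climate features -- over the regions of the
#' reporting countries.  The country label is attached for the
#' country-effect model and country-wise cross-validation.
#'
#' @param calibration Calibration table from [build_calibration_table()].
#' @param substance_id,landcover The substance and class to model.
#' @param regions Landscape table.
#' @param profile The substance's profile.
#' @param climate_features Output of [summarize_climate()].
#' @param retained_climate Character vector of climate features kept by
#'   [prune_correlated()].
#' @param reporting_countries Countries whose regions calibrate the model.
#' @param variant Area variant for the crop predictors (calibration:
#'   `"reported"`).
#' @param inventory Crop inventory.
#' @return A `ppm_design` data frame (`region_id`, `country`, `y`,
#'   predictor columns) with attributes `crop_predictors`,
#'   `climate_predictors`, `substance_id`, `landcover`; or a
#'   `ppm_unmodellable` object when no usable calibration rows exist.
#' @export
assemble_design <- function(calibration, substance_id, landcover, regions,
                            profile, climate_features = NULL,
                            retained_climate = character(),
                            reporting_countries = unique(regions$country),
                            variant = c("reported", "total"),
                            inventory = default_crop_inventory()) {
  variant <- match.arg(variant)
  class_map <- group_landcover_map(inventory)
  rows <- calibration[calibration$substance_id == substance_id &
                        calibration$landcover == landcover &
                        calibration$country %in% reporting_countries, ,
                      drop = FALSE]
  if (nrow(rows) == 0) {
    return(structure(list(substance_id = substance_id,
                          landcover = landcover,
                          reason = "no calibration rows"),
                     class = "ppm_unmodellable"))
  }
  crop_groups <- profile$applicable_groups[
    class_map[profile$applicable_groups] == landcover]
  check_that(length(crop_groups) >= 1, "substance ", substance_id,
             " has no applicable crop group in class '", landcover, "'")
  grouped <- group_crops(regions, crop_group_map(inventory), variant)
  df <- data.frame(region_id = rows$region_id, country = rows$country,
                   y = rows$kg, stringsAsFactors = FALSE)
  idx <- match(df$region_id, grouped$region_id)
  for (g in crop_groups) df[[g]] <- grouped[[g]][idx]
  if (length(retained_climate) > 0) {
    check_that(!is.null(climate_features),
               "`climate_features` required when climate predictors are ",
               "retained")
    cidx <- match(df$region_id, climate_features$region_id)
    for (f in retained_climate) df[[f]] <- climate_features[[f]][cidx]
  }
  check_that(!anyNA(df), "design matrix contains missing values")
  structure(df, crop_predictors = crop_groups,
            climate_predictors = retained_climate,
            substance_id = substance_id, landcover = landcover,
            class = c("ppm_design", "data.frame"))
}

#' @export
print.ppm_design <- function(x, ...) {
  cat("Design matrix:", attr(x, "substance_id"), "/",
      attr(x, "landcover"), "\n",
      nrow(x), "rows;", length(attr(x, "crop_predictors")),
      "crop predictor(s) +", length(attr(x, "climate_predictors")),
      "climate predictor(s)\n")
  invisible(x)
}
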