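#' Build the all-region predictor table for extrapolation
#'
#' Prediction uses total crop extents (regardless of reporting coverage)
#' for every region, together with the regional climate features.
#'
#' @param regions Landscape table (all regions, reporting or not).
#' @param climate_features Output of [summarize_climate()] (optional if no
#'   model uses climate terms).
#' @param inventory Crop inventory.
#' @param variant Area variant; prediction uses `"total"`.
#' @return Data frame: `region_id`, `country`, crop-group area columns,
#'   climate feature columns.
#' @export
build_prediction_table <- function(regions, climate_features = NULL,
                                   inventory = default_crop_inventory(),
                                   variant = "total") {
  grouped <- group_crops(regions, crop_group_map(inventory), variant)
  out <- cbind(data.frame(country = regions$country[
    match(grouped$region_id, regions$region_id)]), grouped)
  out <- out[, c("region_id", "country",
                 setdiff(names(grouped), "region_id"))]
  if (!is.null(climate_features)) {
    idx <- match(out$region_id, climate_features$region_id)
    for (f in setdiff(names(climate_features), "region_id")) {
      out[[f]] <- climate_features[[f]][idx]
    }
  }
  out
}

#' Extrapolate a final model to every region
#'
#' Computes predicted kg for each region from the model's coefficients and
#' the total-extent predictor table.  Negative predictions are clipped to
#' zero (counted in the `clipped` attribute); regions with zero applicable
#' crop area get exactly zero.  The country-augmented M3 model is refused:
#' its country terms make it non-extrapolable by construction.
#'
#' @param model A final `ppm_model` from [run_cascade()].
#' @param prediction_table Output of [build_prediction_table()].
#' @param inventory Crop inventory (identifies which predictors are crop
#'   areas).
#' @return Data frame `region_id`, `country`, `kg` with attribute
#'   `clipped` (number of negative predictions clipped).
#' @export
extrapolate <- function(model, prediction_table,
                        inventory = default_crop_inventory()) {
  check_that(inherits(model, "ppm_model"), "`model` must be a ppm_model")
  check_that(!isTRUE(model$flags$non_extrapolable),
             model$model_id, " is never used for extrapolation ",
             "(country-specific terms)")
  kg <- predict(model, prediction_table)
  clipped <- sum(kg < 0)
  kg[kg < 0] <- 0
  crop_pred <- intersect(model$predictors, unique(inventory$crop_group))
  if (length(crop_pred) > 0) {
    no_area <- rowSums(as.matrix(
      prediction_table[, crop_pred, drop = FALSE])) == 0
    kg[no_area] <- 0
  }
  structure(data.frame(region_id = prediction_table$region_id,
                       country = prediction_table$country, kg = kg,
                       stringsAsFactors = FALSE),
            clipped = clipped)
}

#' Mask predictions where a substance is not authorized
#'
#' Emission is set to exactly zero for every (country, substance) pair
#' whose authorization flag is `FALSE`; authorized pairs pass through
#' unchanged.  The number of masked rows is attached as attribute
#' `masked`.
#'
#' @param predictions Data frame with `country`, `substance_id` and `kg`
#'   columns (any grain).
#' @param auth Authorization table (`country`, `substance_id`,
#'   `authorized`).
#' @return The predictions with masked kg and attribute `masked`.
#' @export
apply_authorization <- function(predictions, auth) {
  check_columns(predictions, c("country", "substance_id", "kg"),
                "`predictions`")
  check_columns(auth, c("country", "substance_id", "authorized"), "`auth`")
  key <- paste(predictions$country, predictions$substance_id)
  akey <- paste(auth$country, auth$substance_id)
  flag <- auth$authorized[match(key, akey)]
  flag[is.na(flag)] <- TRUE  # permissive default: mask only known refusals
  masked <- sum(!flag & predictions$kg != 0)
  predictions$kg[!flag] <- 0
  structure(predictions, masked = masked)
}

#' Assemble the published emission table
#'
#' One row per (region, substance) with the substance's identity fields
#' and `KG_TOT`, the sum of its per-class regional emissions.  Column
#' names and order follow the published schema exactly.
#'
#' @param per_class Data frame `region_id`, `country`, `substance_id`,
#'   `landcover`, `kg` (masked predictions).
#' @param catalog Substance catalog.
#' @return List with `primary` (published schema: Country, NUTS3,
#'   Categories of products, Chemical Class Substance, ID_EUPDB, CAS,
#'   CIPAC, Substances common names, KG_TOT) and `detailed` (adds one
#'   column per land-cover class).
#' @export
assemble_dataset <- function(per_class, catalog) {
  check_columns(per_class, c("region_id", "country", "substance_id",
                             "landcover", "kg"), "`per_class`")
  unknown <- setdiff(unique(per_class$substance_id), catalog$substance_id)
  check_that(length(unknown) == 0, "substance(s) not in catalog: ",
             paste(unknown, collapse = ", "))
  tot <- stats::aggregate(
    per_class["kg"],
    by = per_class[, c("region_id", "country", "substance_id")],
    FUN = sum)
  cat_idx <- match(tot$substance_id, catalog$substance_id)
  primary <- data.frame(
    Country = tot$country,
    NUTS3 = tot$region_id,
    `Categories of products` = catalog$category[cat_idx],
    `Chemical Class Substance` = catalog$chemical_class[cat_idx],
    ID_EUPDB = catalog$ID_EUPDB[cat_idx],
    CAS = catalog$CAS[cat_idx],
    CIPAC = catalog$CIPAC[cat_idx],
    `Substances common names` = catalog$common_name[cat_idx],
    KG_TOT = tot$kg,
    check.names = FALSE, stringsAsFactors = FALSE)
  ord <- order(primary$Country, primary$NUTS3,
               primary$`Substances common names`)
  primary <- primary[ord, ]
  rownames(primary) <- NULL
  detailed <- primary
  for (cl in landcover_classes()) {
    sub <- per_class[per_class$landcover == cl, ]
    key <- paste(detailed$NUTS3, tot$substance_id[ord])
    skey <- paste(sub$region_id, sub$substance_id)
    v <- sub$kg[match(key, skey)]
    v[is.na(v)] <- 0
    detailed[[paste0("KG_", gsub(" ", "_", cl))]] <- v
  }
  list(primary = primary, detailed = detailed)
}

#' Write an emission table in the published CSV schema
#'
#' @param table The `primary` (or `detailed`) emission data frame.
#' @param path Output CSV path (UTF-8, header, "." decimal).
#' @export
write_emissions <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an emission table written by [write_emissions()]
#' @param path CSV path.
#' @return Data frame with the schema's columns.
#' @export
read_emissions <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = c(CAS = "character"))
}
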