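#' Convert commercial-product records to active-substance amounts
#'
#' Where use is reported as commercial products, effective kilograms of
#' each active substance are computed from the product's composition
#' (fraction by mass of each substance).  Records of the same scope and
#' substance are summed.  Products without a known composition are not
#' silently dropped: they are returned in a rejects table.
#'
#' @param product_records Data frame with columns `product`, `kg` plus any
#'   scope columns (e.g. `country`, `scope`, `year`) carried through as
#'   grouping keys.
#' @param composition Data frame with columns `product`, `substance_id`,
#'   `fraction` (mass fractions in \[0, 1\]).
#' @return List with `records` (one row per scope x substance, column `kg`)
#'   and `rejects` (input rows whose product lacks a composition).
#' @export
convert_products_to_as <- function(product_records, composition) {
  check_columns(product_records, c("product", "kg"), "`product_records`")
  check_columns(composition, c("product", "substance_id", "fraction"),
                "`composition`")
  check_that(all(composition$fraction >= 0 & composition$fraction <= 1),
             "composition fractions must lie in [0, 1]")
  known <- product_records$product %in% composition$product
  rejects <- product_records[!known, , drop = FALSE]
  keep <- product_records[known, , drop = FALSE]
  keys <- setdiff(names(keep), c("product", "kg"))
  merged <- merge(keep, composition, by = "product")
  merged$kg <- merged$kg * merged$fraction
  if (nrow(merged) == 0) {
    records <- merged[, c(keys, "substance_id", "kg"), drop = FALSE]
  } else {
    records <- stats::aggregate(
      merged["kg"], by = merged[, c(keys, "substance_id"), drop = FALSE],
      FUN = sum)
  }
  rownames(records) <- rownames(rejects) <- NULL
  list(records = records, rejects = rejects)
}

#' Average reported use over available years
#'
#' Multi-year reports are reduced to a single representative record per
#' scope and substance by the arithmetic mean of the available years; the
#' year field is set to `"multi"`.  Idempotent on single-year input.
#'
#' @param records Reported-use data frame with columns `country`, `scope`,
#'   `substance_id`, `year`, `kg`.
#' @return Data frame with one `"multi"` record per (country, scope,
#'   substance).
#' @export
average_over_years <- function(records) {
  check_columns(records, c("country", "scope", "substance_id", "year", "kg"),
                "`records`")
  out <- stats::aggregate(
    records["kg"],
    by = records[, c("country", "scope", "substance_id"), drop = FALSE],
    FUN = mean)
  out$year <- "multi"
  out <- out[order(out$country, out$scope, out$substance_id),
             c("country", "scope", "substance_id", "year", "kg")]
  rownames(out) <- NULL
  out
}

# ---- CSV loaders -----------------------------------------------------------
# All files are UTF-8, comma-separated, "." decimal.  Loaders enforce the
# type invariants on load and reject invalid rows naming row and column
# rather than coercing.

#' Read and validate a reported-use table
#'
#' @param path CSV with columns `country`, `scope`, `substance_id`,
#'   `year`, `kg` (and optionally `crops`).
#' @return Validated data frame.
#' @export
read_reported_use <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(year = "character"))
  check_columns(df, c("country", "scope", "substance_id", "year", "kg"),
                basename(path))
  bad <- which(!is.finite(df$kg) | df$kg < 0)
  check_that(length(bad) == 0, basename(path), ": negative or non-finite kg",
             " in column 'kg', row(s) ", paste(utils::head(bad, 5),
                                               collapse = ", "))
  key <- paste(df$country, df$scope, df$substance_id, df$year)
  dup <- which(duplicated(key))
  check_that(length(dup) == 0, basename(path),
             ": duplicate (country, scope, substance, year) record at ",
             "row(s) ", paste(utils::head(dup, 5), collapse = ", "))
  df
}

#' Write a reported-use table
#' @param records Reported-use data frame.
#' @param path Output CSV path.
#' @export
write_reported_use <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a region/landscape table
#'
#' @param path CSV written by [write_regions()]: `region_id`, `country`,
#'   `province` plus `total_*` and `reported_*` area columns.
#' @return Validated landscape data frame.
#' @export
read_regions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("region_id", "country", "province"), basename(path))
  dup <- which(duplicated(df$region_id))
  check_that(length(dup) == 0, basename(path),
             ": duplicate region_id at row(s) ",
             paste(utils::head(dup, 5), collapse = ", "))
  for (v in c("total", "reported")) {
    m <- region_areas(df, v)
    bad <- which(m < 0, arr.ind = TRUE)
    check_that(nrow(bad) == 0, basename(path), ": negative area in column '",
               paste0(v, "_", colnames(m)[bad[1, 2]]), "', row ", bad[1, 1])
  }
  tot <- region_areas(df, "total")
  rep <- region_areas(df, "reported")
  common <- intersect(colnames(tot), colnames(rep))
  over <- which(rep[, common, drop = FALSE] >
                  tot[, common, drop = FALSE] * (1 + 1e-9), arr.ind = TRUE)
  check_that(nrow(over) == 0, basename(path),
             ": reported-coverage area exceeds total area in column '",
             paste0("reported_", common[over[1, 2]]), "', row ", over[1, 1])
  df
}

#' Write a region/landscape table
#' @param regions Landscape data frame.
#' @param path Output CSV path.
#' @export
write_regions <- function(regions, path) {
  utils::write.csv(regions, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a substance catalog (identity + applicability + dose weights)
#'
#' The catalog CSV mirrors the published identity fields and adds the
#' crop-group applicability and relative dose weights as semicolon-joined
#' lists.
#'
#' @param catalog Catalog data frame (see [reference_catalog()]).
#' @param doses Dose table (`substance_id`, `crop_group`, `dose`).
#' @param path Output CSV path.
#' @export
write_catalog <- function(catalog, doses, path) {
  rows <- lapply(catalog$substance_id, function(s) {
    d <- doses[doses$substance_id == s, ]
    data.frame(crop_groups = paste(d$crop_group, collapse = ";"),
               dose_weights = paste(format(d$dose, trim = TRUE,
                                           scientific = FALSE),
                                    collapse = ";"))
  })
  utils::write.csv(cbind(catalog, do.call(rbind, rows)), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a substance catalog
#'
#' @param path CSV written by [write_catalog()].
#' @return List with `catalog` and `doses` data frames.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE,
                        colClasses = c(CAS = "character"))
  id_cols <- c("substance_id", "common_name", "category", "chemical_class",
               "CAS", "CIPAC", "ID_EUPDB")
  check_columns(df, c(id_cols, "crop_groups", "dose_weights"),
                basename(path))
  dup <- which(duplicated(df$substance_id))
  check_that(length(dup) == 0, basename(path),
             ": duplicate substance_id at row(s) ",
             paste(utils::head(dup, 5), collapse = ", "))
  doses <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    groups <- strsplit(df$crop_groups[i], ";", fixed = TRUE)[[1]]
    w <- as.numeric(strsplit(df$dose_weights[i], ";", fixed = TRUE)[[1]])
    check_that(length(groups) >= 1 && all(nzchar(groups)),
               basename(path), ": no applicable crop group in column ",
               "'crop_groups', row ", i)
    check_that(length(w) == length(groups) && all(is.finite(w) & w >= 0),
               basename(path), ": invalid dose_weights, row ", i)
    data.frame(substance_id = df$substance_id[i], crop_group = groups,
               dose = w, stringsAsFactors = FALSE)
  }))
  rownames(doses) <- NULL
  list(catalog = df[, id_cols], doses = doses)
}

#' Read a country x substance authorization table
#'
#' Missing (country, substance) pairs receive the default policy
#' (authorized, permissive: only known non-authorizations are masked) and
#' are reported via a message.
#'
#' @param path CSV with columns `country`, `substance_id`, `authorized`
#'   (logical or 0/1).
#' @param countries,substances Complete sets over which the matrix is
#'   totalized.
#' @param default Flag applied to pairs absent from the file.
#' @return Data frame covering every (country, substance) pair.
#' @export
read_authorizations <- function(path, countries, substances,
                                default = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("country", "substance_id", "authorized"),
                basename(path))
  df$authorized <- as.logical(df$authorized)
  check_that(!anyNA(df$authorized), basename(path),
             ": non-logical value in column 'authorized'")
  full <- expand.grid(country = countries, substance_id = substances,
                      stringsAsFactors = FALSE)
  m <- merge(full, df, by = c("country", "substance_id"), all.x = TRUE)
  n_default <- sum(is.na(m$authorized))
  if (n_default > 0) {
    message(n_default, " (country, substance) pair(s) absent from ",
            basename(path), "; default authorized = ", default, " applied")
    m$authorized[is.na(m$authorized)] <- default
  }
  m[order(m$country, m$substance_id), ]
}

#' Write an authorization table
#' @param auth Authorization data frame.
#' @param path Output CSV path.
#' @export
write_authorizations <- function(auth, path) {
  utils::write.csv(auth, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
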