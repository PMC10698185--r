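#' Construct a synthetic ground truth for the use-generation process
#'
#' Bundles the quantities that define how much of each active substance is
#' applied where: a dose (kg/ha) per (substance, crop group), optional
#' dimensionless climate-modulation coefficients per (substance, climate
#' feature), and a log-scale noise standard deviation.  Regional true use is
#' generated as dose x area x exp(climate linear term) x exp(noise), so use
#' can never go negative.
#'
#' @param doses Data frame with columns `substance_id`, `crop_group`,
#'   `dose` (kg/ha, >= 0).  Every substance must have at least one strictly
#'   positive dose.
#' @param climate_coefs Optional data frame with columns `substance_id`,
#'   `feature`, `coef`; coefficients multiply z-scored regional climate
#'   features on the log scale.  `NULL` means no climate modulation.
#' @param noise_sd Non-negative log-scale standard deviation of the
#'   multiplicative noise.
#' @param seed Integer seed; fixed seed makes every generated artifact
#'   reproducible.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(doses, climate_coefs = NULL, noise_sd = 0,
                            seed = 42L) {
  check_columns(doses, c("substance_id", "crop_group", "dose"), "`doses`")
  check_that(all(doses$dose >= 0), "doses must be >= 0")
  pos <- tapply(doses$dose, doses$substance_id, function(d) any(d > 0))
  check_that(all(pos), "every substance needs at least one positive dose; ",
             "offending: ", paste(names(pos)[!pos], collapse = ", "))
  if (!is.null(climate_coefs)) {
    check_columns(climate_coefs, c("substance_id", "feature", "coef"),
                  "`climate_coefs`")
  }
  check_that(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd >= 0,
             "`noise_sd` must be a non-negative scalar")
  structure(list(doses = doses, climate_coefs = climate_coefs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Construct a reporting scheme
#'
#' Describes how each country reports its use: at which spatial resolution
#' (country, province or region level), which crop codes it omits from its
#' reports, and which countries do not report at all.
#'
#' @param resolution Named character vector, one entry per reporting
#'   country, values in `c("country", "province", "region")`.
#' @param unreported_crops Named list of character vectors of crop codes a
#'   country omits; countries absent from the list omit nothing.
#' @param non_reporting Character vector of countries that report nothing.
#' @return An object of class `reporting_scheme`.
#' @export
reporting_scheme <- function(resolution, unreported_crops = list(),
                             non_reporting = character()) {
  check_that(length(resolution) > 0 && !is.null(names(resolution)) &&
               all(nzchar(names(resolution))),
             "`resolution` must be a named character vector")
  bad <- setdiff(resolution, c("country", "province", "region"))
  check_that(length(bad) == 0, "unknown resolution level(s): ",
             paste(bad, collapse = ", "))
  extra <- setdiff(names(unreported_crops), names(resolution))
  check_that(length(extra) == 0,
             "`unreported_crops` names countries outside the scheme: ",
             paste(extra, collapse = ", "))
  structure(list(resolution = resolution,
                 unreported_crops = unreported_crops,
                 non_reporting = as.character(non_reporting)),
            class = "reporting_scheme")
}

#' Generate a synthetic landscape of regions and crop areas
#'
#' Emulates the statistical structure of regional agricultural area tables:
#' per-region crop areas drawn log-normal (heavy-tailed, like real
#' agricultural statistics), in two variants -- `total_<code>` areas used
#' for prediction and `reported_<code>` areas (the extent over which use is
#' actually reported) used for calibration.  Regions are grouped into
#' provinces of contiguous regions within each country.
#'
#' @param n_countries,regions_per_country Positive counts.
#' @param crop_codes Character vector of unique crop codes.
#' @param seed Integer seed.
#' @param area_median Median crop area in hectares (log-normal location).
#' @param area_log_sd Log-scale standard deviation of crop areas.
#' @param coverage_fraction Fraction of the total area covered by
#'   reporting, in (0, 1]; 1 means reported-coverage areas equal totals.
#' @param regions_per_province Number of contiguous regions per province.
#' @param sparsity Probability that a given crop is absent (area 0) from a
#'   given region.
#' @return Data frame with one row per region: `region_id`, `country`,
#'   `province`, then `total_<code>` and `reported_<code>` area columns
#'   (ha).
#' @export
generate_landscape <- function(n_countries, regions_per_country, crop_codes,
                               seed = 42L, area_median = 500,
                               area_log_sd = 1.0, coverage_fraction = 1.0,
                               regions_per_province = 2L, sparsity = 0) {
  n_countries <- check_count(n_countries, "n_countries")
  regions_per_country <- check_count(regions_per_country,
                                     "regions_per_country")
  check_that(length(crop_codes) >= 1 && !anyDuplicated(crop_codes),
             "`crop_codes` must be non-empty and unique")
  check_that(coverage_fraction > 0 && coverage_fraction <= 1,
             "`coverage_fraction` must be in (0, 1]")
  countries <- sprintf("CN%02d", seq_len(n_countries))
  with_seed(seed, {
    rows <- lapply(countries, function(co) {
      ridx <- seq_len(regions_per_country)
      prov <- sprintf("%s_P%02d", co,
                      ceiling(ridx / regions_per_province))
      data.frame(region_id = sprintf("%s_R%03d", co, ridx),
                 country = co, province = prov,
                 stringsAsFactors = FALSE)
    })
    regions <- do.call(rbind, rows)
    n <- nrow(regions)
    p <- length(crop_codes)
    total <- matrix(stats::rlnorm(n * p, meanlog = log(area_median),
                                  sdlog = area_log_sd),
                    nrow = n, ncol = p)
    if (sparsity > 0) {
      total[matrix(stats::runif(n * p) < sparsity, n, p)] <- 0
    }
    reported <- total * coverage_fraction
    colnames(total) <- paste0("total_", crop_codes)
    colnames(reported) <- paste0("reported_", crop_codes)
    cbind(regions, as.data.frame(total), as.data.frame(reported))
  })
}

#' Extract a region x crop area matrix from a landscape table
#'
#' @param regions Landscape table from [generate_landscape()] or
#'   [read_regions()].
#' @param variant `"total"` (prediction extents) or `"reported"`
#'   (calibration extents).
#' @return Numeric matrix, rownames = region ids, colnames = crop codes.
#' @export
region_areas <- function(regions, variant = c("total", "reported")) {
  variant <- match.arg(variant)
  cols <- grep(paste0("^", variant, "_"), names(regions), value = TRUE)
  check_that(length(cols) > 0, "no `", variant, "_*` area columns found")
  m <- as.matrix(regions[, cols, drop = FALSE])
  rownames(m) <- regions$region_id
  colnames(m) <- sub(paste0("^", variant, "_"), "", cols)
  m
}

#' Generate per-region climate cell samples
#'
#' Emulates gridded monthly climate summaries: for each region,
#' `cells_per_region` cell samples of 12 monthly mean temperatures and 12
#' monthly mean precipitations (24 variables).  Each region's monthly
#' climate departs from the continental seasonal cycle by a single smooth
#' monthly anomaly (a cross-region gradient plus a regional random
#' anomaly) that drives temperature and precipitation jointly, and the
#' within-region cell dispersion follows a fixed quantile pattern whose
#' scale is tied to the same anomaly.  Regional summary statistics of one
#' month are therefore strongly collinear with each other -- the
#' redundancy structure that makes correlation pruning of real climate
#' summaries collapse each variable's statistics -- while different
#' months stay clearly distinguishable.  Precipitation is truncated at
#' zero.
#'
#' @param regions Landscape table.
#' @param cells_per_region Cells sampled per region (>= 1).
#' @param seed Integer seed.
#' @param gradient_amplitude Amplitude (degrees C) of the smooth
#'   cross-region gradient; 0 with `anomaly_sd = 0` makes all regions
#'   identical.
#' @param anomaly_sd Sd (degrees C) of the independent regional monthly
#'   anomalies.
#' @param prec_scale mm of precipitation anomaly per degree of the shared
#'   monthly anomaly.
#' @param spread_base,spread_sens Base within-region dispersion (degrees)
#'   and its log-linear sensitivity to the monthly anomaly.
#' @param cell_noise_sd Optional unstructured cell-level noise sd
#'   (default 0).
#' @return Long data frame: `region_id`, `cell`, `variable`, `value`, with
#'   variables `temp_m01..temp_m12`, `prec_m01..prec_m12`.
#' @export
generate_climate <- function(regions, cells_per_region = 5L, seed = 42L,
                             gradient_amplitude = 8, anomaly_sd = 2,
                             prec_scale = 4, spread_base = 2,
                             spread_sens = 0.1, cell_noise_sd = 0) {
  check_that(is.data.frame(regions) && nrow(regions) > 0,
             "`regions` must be a non-empty region table")
  cells_per_region <- check_count(cells_per_region, "cells_per_region")
  n <- nrow(regions)
  nc <- cells_per_region
  pos <- if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1)
  months <- 1:12
  # fixed standardized cell pattern (equally spaced normal quantiles)
  q <- if (nc == 1) 0 else stats::qnorm((seq_len(nc) - 0.5) / nc)
  with_seed(seed, {
    anom <- gradient_amplitude * matrix(pos, n, 12) +
      anomaly_sd * matrix(stats::rnorm(n * 12), n, 12)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      temp <- 10 + 8 * sin(2 * pi * (months - 4) / 12) + anom[i, ]
      prec <- 80 + 30 * cos(2 * pi * (months - 1) / 12) +
        prec_scale * anom[i, ]
      spread <- spread_base * exp(spread_sens * anom[i, ])
      tm <- rep(temp, each = nc) + rep(spread, each = nc) * rep(q, 12)
      pm <- rep(prec, each = nc) + 5 * rep(spread, each = nc) * rep(q, 12)
      if (cell_noise_sd > 0) {
        tm <- tm + stats::rnorm(12 * nc, sd = cell_noise_sd)
        pm <- pm + stats::rnorm(12 * nc, sd = 5 * cell_noise_sd)
      }
      out[[i]] <- data.frame(
        region_id = regions$region_id[i],
        cell = rep(seq_len(nc), times = 24),
        variable = rep(c(sprintf("temp_m%02d", months),
                         sprintf("prec_m%02d", months)),
                       each = nc),
        value = c(tm, pmax(0, pm)),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Simulate true regional use of every substance
#'
#' The generative counterpart of the linear model: per region, substance
#' and crop code, true applied mass is dose(crop group) x total area(crop)
#' x exp(climate linear term) x exp(noise), with one noise draw per
#' (region, substance).  Setting `noise_sd = 0` and no climate coefficients
#' makes the output exactly dose x area.
#'
#' @param truth A [synthetic_truth()] object.
#' @param regions Landscape table.
#' @param crop_grouping Named vector mapping crop code to crop group (see
#'   [crop_group_map()]).
#' @param climate_features Optional region x feature data frame (as from
#'   [summarize_climate()]); required when `truth$climate_coefs` is set.
#'   Features are z-scored before entering the log-linear term.
#' @param inventory Crop inventory supplying the group-to-class map.
#' @return Data frame: `region_id`, `country`, `substance_id`, `crop_code`,
#'   `crop_group`, `landcover`, `kg`.
#' @export
simulate_true_use <- function(truth, regions,
                              crop_grouping = crop_group_map(),
                              climate_features = NULL,
                              inventory = default_crop_inventory()) {
  check_that(inherits(truth, "synthetic_truth"),
             "`truth` must be a synthetic_truth object")
  areas <- region_areas(regions, "total")
  codes <- colnames(areas)
  known_groups <- unique(crop_grouping[codes])
  bad <- setdiff(unique(truth$doses$crop_group), known_groups)
  check_that(length(bad) == 0,
             "dose references crop group(s) with no crop present in the ",
             "landscape: ", paste(bad, collapse = ", "))
  class_map <- group_landcover_map(inventory)
  subs <- unique(truth$doses$substance_id)
  n <- nrow(regions)

  clim_term <- matrix(0, nrow = n, ncol = length(subs),
                      dimnames = list(regions$region_id, subs))
  if (!is.null(truth$climate_coefs) && nrow(truth$climate_coefs) > 0) {
    check_that(!is.null(climate_features),
               "`climate_features` required when truth has climate_coefs")
    feat <- as.matrix(climate_features[match(regions$region_id,
                                             climate_features$region_id),
                                       truth$climate_coefs$feature,
                                       drop = FALSE])
    z <- scale(feat)
    z[is.nan(z)] <- 0
    for (j in seq_len(nrow(truth$climate_coefs))) {
      cc <- truth$climate_coefs[j, ]
      clim_term[, cc$substance_id] <- clim_term[, cc$substance_id] +
        cc$coef * z[, j]
    }
  }

  with_seed(truth$seed, {
    noise <- matrix(0, nrow = n, ncol = length(subs),
                    dimnames = list(regions$region_id, subs))
    if (truth$noise_sd > 0) {
      noise[] <- stats::rnorm(n * length(subs), sd = truth$noise_sd)
    }
    out <- vector("list", length(subs))
    for (si in seq_along(subs)) {
      s <- subs[si]
      d <- truth$doses[truth$doses$substance_id == s & truth$doses$dose > 0, ]
      dose_by_code <- d$dose[match(crop_grouping[codes], d$crop_group)]
      use_codes <- which(!is.na(dose_by_code))
      if (length(use_codes) == 0) next
      mult <- exp(clim_term[, s] + noise[, s])
      kg <- sweep(areas[, use_codes, drop = FALSE], 2,
                  dose_by_code[use_codes], `*`) * mult
      grp <- unname(crop_grouping[codes[use_codes]])
      out[[si]] <- data.frame(
        region_id = rep(regions$region_id, times = length(use_codes)),
        country = rep(regions$country, times = length(use_codes)),
        substance_id = s,
        crop_code = rep(codes[use_codes], each = n),
        crop_group = rep(grp, each = n),
        landcover = rep(unname(class_map[grp]), each = n),
        kg = as.vector(kg),
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Aggregate code-level true use to (region, substance, class) totals
#'
#' @param true_use Output of [simulate_true_use()].
#' @return Data frame `region_id`, `country`, `substance_id`, `landcover`,
#'   `kg`.
#' @export
true_use_by_class <- function(true_use) {
  agg <- stats::aggregate(kg ~ region_id + country + substance_id + landcover,
                          data = true_use, FUN = sum)
  agg <- agg[order(agg$substance_id, agg$region_id, agg$landcover), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Simulate what each country reports
#'
#' Aggregates true regional use up to each country's reporting resolution
#' (country, province or region scope), after removing the contributions of
#' crops the country does not report on; non-reporting countries are
#' absent.  Optionally replicates records over several years with
#' independent multiplicative log-normal noise.
#'
#' @param true_use Code-level true use from [simulate_true_use()].
#' @param scheme A [reporting_scheme()].
#' @param regions Landscape table (supplies the region-to-province map).
#' @param years Optional integer vector of reporting years; `NULL` emits a
#'   single `"multi"` record per scope and substance.
#' @param year_noise_sd Log-scale sd of independent per-year noise.
#' @param seed Seed for the per-year noise.
#' @return Data frame of reported-use records: `country`, `scope`,
#'   `substance_id`, `year`, `kg`.
#' @export
simulate_reporting <- function(true_use, scheme, regions, years = NULL,
                               year_noise_sd = 0, seed = 42L) {
  check_that(inherits(scheme, "reporting_scheme"),
             "`scheme` must be a reporting_scheme object")
  rep_countries <- setdiff(names(scheme$resolution), scheme$non_reporting)
  u <- true_use[true_use$country %in% rep_countries, , drop = FALSE]
  # remove unreported-crop contributions before any summation
  for (co in names(scheme$unreported_crops)) {
    drop <- scheme$unreported_crops[[co]]
    u <- u[!(u$country == co & u$crop_code %in% drop), , drop = FALSE]
  }
  prov <- stats::setNames(regions$province, regions$region_id)
  u$scope <- ifelse(scheme$resolution[u$country] == "country", u$country,
                    ifelse(scheme$resolution[u$country] == "province",
                           unname(prov[u$region_id]), u$region_id))
  agg <- stats::aggregate(kg ~ country + scope + substance_id, data = u,
                          FUN = sum)
  agg <- agg[order(agg$country, agg$scope, agg$substance_id), , drop = FALSE]
  rownames(agg) <- NULL
  if (is.null(years)) {
    agg$year <- "multi"
    return(agg[, c("country", "scope", "substance_id", "year", "kg")])
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(years, function(y) {
      r <- agg
      r$year <- as.character(y)
      if (year_noise_sd > 0) {
        r$kg <- r$kg * exp(stats::rnorm(nrow(r), sd = year_noise_sd))
      }
      r
    }))
    rownames(out) <- NULL
    out[, c("country", "scope", "substance_id", "year", "kg")]
  })
}

#' Generate climate-like features in correlated blocks
#'
#' A fixture generator for collinearity-pruning checks: `k` blocks of
#' `per_block` features each; features within a block are near-duplicates
#' (|r| close to 1) while features from different blocks are nearly
#' independent.
#'
#' @param n Number of rows (regions).
#' @param k Number of blocks.
#' @param per_block Features per block.
#' @param seed Integer seed.
#' @param within_noise Sd of the perturbation distinguishing features
#'   within a block (small => high within-block correlation).
#' @return Data frame with `region_id` and `k * per_block` feature columns
#'   named `b<block>_f<j>`.
#' @export
block_feature_fixture <- function(n = 60, k = 4, per_block = 5, seed = 7L,
                                  within_noise = 0.05) {
  with_seed(seed, {
    base <- matrix(stats::rnorm(n * k), n, k)
    cols <- list()
    for (b in seq_len(k)) {
      for (j in seq_len(per_block)) {
        cols[[sprintf("b%d_f%d", b, j)]] <-
          base[, b] + stats::rnorm(n, sd = within_noise)
      }
    }
    cbind(data.frame(region_id = sprintf("R%03d", seq_len(n)),
                     stringsAsFactors = FALSE),
          as.data.frame(cols))
  })
}
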