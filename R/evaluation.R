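#' Goodness-of-fit metrics for observed vs predicted use
#'
#' Computes the five normalized metrics used to compare models across
#' substances with very different magnitudes:
#' \itemize{
#'   \item SMAPE = mean(2|y_hat - y| / (|y| + |y_hat|)), on the \[0, 2\]
#'     scale, with 0/0 terms counted as 0;
#'   \item NSE = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2); 1 is a
#'     perfect prediction, 0 matches predicting the observed mean, and
#'     positive values mean the model beats the mean;
#'   \item NRMSE = RMSE / mean(y);
#'   \item NMAE = MAE / mean(y);
#'   \item R2: squared Pearson correlation of observed and predicted (the
#'     cross-validation-safe reading), or the coefficient of
#'     determination when `r2_method = "cod"`.
#' }
#'
#' @param observed,predicted Equal-length numeric vectors (kg), length
#'   >= 2.
#' @param r2_method `"pearson"` (default) or `"cod"`.
#' @return Named numeric vector with elements `SMAPE`, `NSE`, `NRMSE`,
#'   `R2`, `NMAE`.  `NSE` is `NA` when the observed values are all
#'   identical (undefined); `R2` is `NA` when either vector is constant.
#' @export
compute_metrics <- function(observed, predicted,
                            r2_method = c("pearson", "cod")) {
  r2_method <- match.arg(r2_method)
  check_that(length(observed) == length(predicted),
             "observed and predicted must have equal length")
  check_that(length(observed) >= 2, "need at least 2 observations")
  y <- observed; yh <- predicted
  denom <- abs(y) + abs(yh)
  terms <- ifelse(denom == 0, 0, 2 * abs(yh - y) / denom)
  smape <- mean(terms)
  ss_res <- sum((y - yh)^2)
  ss_tot <- sum((y - mean(y))^2)
  nse <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  nrmse <- sqrt(mean((y - yh)^2)) / mean(y)
  nmae <- mean(abs(y - yh)) / mean(y)
  r2 <- if (r2_method == "pearson") {
    if (stats::sd(y) == 0 || stats::sd(yh) == 0) NA_real_ else
      stats::cor(y, yh)^2
  } else {
    if (ss_tot == 0) NA_real_ else max(0, 1 - ss_res / ss_tot)
  }
  c(SMAPE = smape, NSE = nse, NRMSE = nrmse, R2 = r2, NMAE = nmae)
}

metric_names <- c("SMAPE", "NSE", "NRMSE", "R2", "NMAE")

# Assemble a cv_report from a predictions table carrying rep/fold labels.
build_cv_report <- function(predictions, k, repetitions, seed, type) {
  per_fold <- do.call(rbind, lapply(
    split(predictions, predictions[, c("rep", "fold")], drop = TRUE),
    function(d) {
      # singleton folds (k = n) carry no per-fold metrics; the pooled
      # per-repetition summary still covers them
      m <- if (nrow(d) >= 2) compute_metrics(d$observed, d$predicted) else
        stats::setNames(rep(NA_real_, length(metric_names)), metric_names)
      cbind(data.frame(rep = d$rep[1], fold = d$fold[1],
                       n = nrow(d)), as.data.frame(as.list(m)))
    }))
  summary <- do.call(rbind, lapply(split(predictions, predictions$rep),
                                   function(d) {
    m <- compute_metrics(d$observed, d$predicted)
    cbind(data.frame(rep = d$rep[1]), as.data.frame(as.list(m)))
  }))
  rownames(per_fold) <- rownames(summary) <- NULL
  structure(list(type = type, k = k, repetitions = repetitions,
                 seed = seed, predictions = predictions,
                 per_fold = per_fold, summary = summary,
                 normalizer = "mean(observed)"),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$type, "cross-validation:", x$k, "fold(s) x", x$repetitions,
      "repetition(s)\n")
  means <- colMeans(x$summary[, metric_names, drop = FALSE], na.rm = TRUE)
  print(round(means, 4))
  invisible(x)
}

#' Repeated k-fold cross-validation of a model recipe
#'
#' Shuffles the design rows into `k` folds (disjoint, exhaustive, sizes
#' differing by at most one), refits the recipe on the k-1 training folds
#' and predicts the held-out fold; the whole procedure is repeated
#' `repetitions` times with fresh fold assignments, so every observation
#' is validated exactly `repetitions` times.  Defaults follow the
#' reference protocol of 10 folds repeated 100 times.
#'
#' @param design A `ppm_design` (any data frame with a `y` column and the
#'   recipe's predictor columns works).
#' @param recipe Function `design -> model` with a `predict` method (see
#'   e.g. [fit_m1()]).
#' @param k Number of folds (2..n).
#' @param repetitions Number of repeats.
#' @param seed Seed for the fold shuffling.
#' @return A `cv_report`: per-fold and per-repetition (pooled) metrics,
#'   the full held-out prediction table, and the fold-assignment record.
#' @export
repeated_kfold <- function(design, recipe, k = 10, repetitions = 100,
                           seed = 1L) {
  n <- nrow(design)
  check_that(k >= 2 && k <= n, "`k` must be in 2..nrow(design) (= ", n, ")")
  with_seed(seed, {
    preds <- vector("list", repetitions)
    for (r in seq_len(repetitions)) {
      fold_of <- sample(rep(seq_len(k), length.out = n))
      rep_preds <- vector("list", k)
      for (f in seq_len(k)) {
        test <- which(fold_of == f)
        fit <- recipe(design[-test, , drop = FALSE])
        rep_preds[[f]] <- data.frame(
          rep = r, fold = f, row = test,
          region_id = if ("region_id" %in% names(design))
            design$region_id[test] else as.character(test),
          observed = design$y[test],
          predicted = predict(fit, design[test, , drop = FALSE]),
          stringsAsFactors = FALSE)
      }
      preds[[r]] <- do.call(rbind, rep_preds)
    }
    build_cv_report(do.call(rbind, preds), k, repetitions, seed,
                    "repeated k-fold")
  })
}

#' Leave-one-country-out cross-validation
#'
#' One fold per country: predictions for a country's regions are made by
#' a model fitted without any row of that country, probing whether use
#' patterns transfer across countries (the situation faced when
#' extrapolating to non-reporting countries).
#'
#' @param design A `ppm_design` with a `country` column (>= 2 countries).
#' @param recipe Function `design -> model` with a `predict` method.
#' @return A `cv_report` whose `per_fold` table carries one block per
#'   country (column `country`).
#' @export
leave_one_country_out <- function(design, recipe) {
  countries <- unique(design$country)
  check_that(length(countries) >= 2,
             "need >= 2 countries for country-wise cross-validation")
  preds <- lapply(seq_along(countries), function(i) {
    co <- countries[i]
    test <- which(design$country == co)
    fit <- recipe(design[-test, , drop = FALSE])
    data.frame(rep = 1L, fold = i, country = co, row = test,
               region_id = if ("region_id" %in% names(design))
                 design$region_id[test] else as.character(test),
               observed = design$y[test],
               predicted = predict(fit, design[test, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  predictions <- do.call(rbind, preds)
  report <- build_cv_report(predictions, k = length(countries),
                            repetitions = 1L, seed = NA_integer_,
                            type = "leave-one-country-out")
  # label per-fold blocks with their country
  report$per_fold$country <-
    countries[report$per_fold$fold]
  report
}

#' External comparison of modeled vs independently reported amounts
#'
#' The comparison used against aggregated external statistics: entries are
#' joined on their keys, then per group the modeled-to-reported ratio of
#' summed amounts, the median and median absolute deviation of the
#' per-entry log10 deviations (both sides incremented by 1 kg before the
#' log), and the fraction of entries within one order of magnitude
#' (|log10 deviation| <= 1, boundary inclusive) are reported.
#'
#' @param estimates Data frame with key columns and a `modeled` column
#'   (kg).
#' @param reference Data frame with key columns and a `reported` column
#'   (kg).
#' @param group_keys Character vector of key columns defining the groups
#'   (e.g. country, category); entries are joined on all shared key
#'   columns.
#' @return Data frame: one row per group with `reported`, `modeled`,
#'   `ratio`, `median_log_dev`, `mad_log_dev`, `frac_within_oom`, `n`.
#' @export
compare_external <- function(estimates, reference, group_keys) {
  check_columns(estimates, c(group_keys, "modeled"), "`estimates`")
  check_columns(reference, c(group_keys, "reported"), "`reference`")
  value_cols <- c("modeled", "reported")
  join_keys <- intersect(setdiff(names(estimates), value_cols),
                         setdiff(names(reference), value_cols))
  merged <- merge(estimates[, c(join_keys, "modeled")],
                  reference[, c(join_keys, "reported")], by = join_keys)
  check_that(nrow(merged) >= 1, "no overlapping keys between estimates ",
             "and reference")
  merged$log_dev <- log10(merged$modeled + 1) - log10(merged$reported + 1)
  out <- do.call(rbind, lapply(
    split(merged, merged[, group_keys, drop = FALSE], drop = TRUE),
    function(g) {
      rep_sum <- sum(g$reported)
      cbind(g[1, group_keys, drop = FALSE],
            data.frame(
              reported = rep_sum, modeled = sum(g$modeled),
              ratio = if (rep_sum > 0) sum(g$modeled) / rep_sum else
                NA_real_,
              median_log_dev = stats::median(g$log_dev),
              mad_log_dev = stats::mad(g$log_dev),
              frac_within_oom = mean(abs(g$log_dev) <= 1),
              n = nrow(g)))
    }))
  rownames(out) <- NULL
  out
}

#' Write a cross-validation report to CSV
#'
#' Serializes the per-fold metric table (one row per fold and repetition)
#' and a per-repetition summary; the normalizer convention is recorded in
#' both files.
#'
#' @param report A `cv_report`.
#' @param path Base path; `<path>_folds.csv` and `<path>_summary.csv` are
#'   written.
#' @return The two paths, invisibly.
#' @export
write_cv_report <- function(report, path) {
  folds <- report$per_fold
  folds$normalizer <- report$normalizer
  summary <- report$summary
  summary$normalizer <- report$normalizer
  p1 <- paste0(path, "_folds.csv")
  p2 <- paste0(path, "_summary.csv")
  utils::write.csv(folds, p1, row.names = FALSE)
  utils::write.csv(summary, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
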