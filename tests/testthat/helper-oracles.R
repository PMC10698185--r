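# Independent brute-force oracles used to check the package's fitting and
# metric code.  These deliberately share no code path with the package.

# Normal-equation OLS solve (with intercept column).
ols_oracle <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  solve(t(xm) %*% xm, t(xm) %*% y)[, 1]
}

# Global NNLS (through origin) by exhaustive active-set enumeration: every
# feasible subset-OLS solution is a feasible point, and the optimum is one
# of them.
nnls_oracle <- function(x, y) {
  x <- as.matrix(x)
  p <- ncol(x)
  best <- list(rss = sum(y^2), beta = rep(0, p))  # empty support
  for (size in seq_len(p)) {
    for (s in utils::combn(p, size, simplify = FALSE)) {
      xs <- x[, s, drop = FALSE]
      b <- tryCatch(solve(t(xs) %*% xs, t(xs) %*% y)[, 1],
                    error = function(e) NULL)
      if (is.null(b) || any(b < 0)) next
      rss <- sum((y - xs %*% b)^2)
      if (rss < best$rss - 1e-12) {
        beta <- rep(0, p)
        beta[s] <- b
        best <- list(rss = rss, beta = beta)
      }
    }
  }
  names(best$beta) <- colnames(x)
  best$beta
}

# Exhaustive best-subset search under AIC = n ln(RSS/n) + 2(k+1).
best_subset_aic_oracle <- function(design, predictors) {
  n <- nrow(design)
  best <- NULL
  for (size in 0:length(predictors)) {
    sets <- if (size == 0) list(character()) else
      utils::combn(predictors, size, simplify = FALSE)
    for (s in sets) {
      rhs <- if (length(s) == 0) "1" else
        paste(sprintf("`%s`", s), collapse = " + ")
      fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = design)
      aic <- n * log(sum(stats::residuals(fit)^2) / n) +
        2 * (length(s) + 1)
      if (is.null(best) || aic < best$aic) best <- list(aic = aic, set = s)
    }
  }
  best
}

# Metric formulas coded independently, loops and all.
metrics_oracle <- function(y, yh) {
  n <- length(y)
  smape_terms <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(y[i]) + abs(yh[i])
    smape_terms[i] <- if (d == 0) 0 else 2 * abs(yh[i] - y[i]) / d
  }
  sse <- sum((y - yh)^2)
  sst <- sum((y - mean(y))^2)
  list(SMAPE = sum(smape_terms) / n,
       NSE = if (sst == 0) NA_real_ else 1 - sse / sst,
       NRMSE = sqrt(sse / n) / mean(y),
       NMAE = sum(abs(y - yh)) / n / mean(y),
       R2 = suppressWarnings(stats::cor(y, yh))^2)
}

# Direct leave-one-out predictions with an arbitrary recipe.
loo_oracle <- function(design, recipe) {
  vapply(seq_len(nrow(design)), function(i) {
    fit <- recipe(design[-i, , drop = FALSE])
    predict(fit, design[i, , drop = FALSE])
  }, numeric(1))
}

# Build a ppm_design directly: y = intercept + X beta (+ mult. log-noise),
# X log-normal like crop areas.
make_design <- function(n, beta, sigma = 0, seed = 1, n_countries = 4,
                        intercept = 0, climate = NULL,
                        landcover = "arable land",
                        substance_id = "SX") {
  p <- length(beta)
  preds <- if (is.null(names(beta))) paste0("crop", seq_len(p)) else
    names(beta)
  set.seed(seed)
  x <- matrix(rlnorm(n * p, log(500), 1), n, p,
              dimnames = list(NULL, preds))
  y <- as.numeric(intercept + x %*% beta)
  if (sigma > 0) y <- y * exp(rnorm(n, sd = sigma))
  df <- data.frame(region_id = sprintf("R%04d", seq_len(n)),
                   country = rep(sprintf("CN%02d", seq_len(n_countries)),
                                 length.out = n),
                   y = y, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x))
  climate_preds <- character()
  if (!is.null(climate)) {
    for (nm in names(climate)) df[[nm]] <- climate[[nm]]
    climate_preds <- names(climate)
  }
  structure(df, crop_predictors = preds, climate_predictors = climate_preds,
            substance_id = substance_id, landcover = landcover,
            class = c("ppm_design", "data.frame"))
}
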