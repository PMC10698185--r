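# The regression cascade: six linear-model variants per substance x
# land-cover class, a stepwise-AIC selector, and the deterministic policy
# choosing the final extrapolation model.

# Least-squares AIC on the profile scale: n ln(RSS/n) + 2 edf, where edf
# counts estimated mean parameters (predictors + intercept if present).
# This matches stats::extractAIC() for lm fits.
ls_aic <- function(n, rss, edf) n * log(rss / n) + 2 * edf

design_predictors <- function(design) {
  c(attr(design, "crop_predictors"), attr(design, "climate_predictors"))
}

predictor_formula <- function(predictors, intercept = TRUE,
                              env = parent.frame()) {
  rhs <- if (length(predictors) == 0) "1" else
    paste(sprintf("`%s`", predictors), collapse = " + ")
  stats::as.formula(paste("y ~", rhs, if (!intercept) "- 1" else ""),
                    env = env)
}

# TRUE when a fit is numerically perfect relative to the response scale;
# stepwise selection on such fits is meaningless (and stats::step warns).
essentially_perfect <- function(fit, y) {
  sqrt(mean(stats::residuals(fit)^2)) <
    1e-10 * (mean(abs(y)) + .Machine$double.eps)
}

new_ppm_model <- function(model_id, intercept, coefficients, sigma, aic,
                          fit = NULL, flags = list()) {
  defaults <- list(country_specific = FALSE, has_negative_coef = FALSE,
                   influential_outliers = character(),
                   non_extrapolable = FALSE)
  flags <- utils::modifyList(defaults, flags)
  flags$has_negative_coef <- any(coefficients < 0)
  structure(list(model_id = model_id, intercept = intercept,
                 coefficients = coefficients, sigma = sigma, aic = aic,
                 predictors = names(coefficients), fit = fit,
                 flags = flags),
            class = "ppm_model")
}

#' @export
print.ppm_model <- function(x, ...) {
  cat(x$model_id, "model:", length(x$coefficients), "predictor(s),",
      "intercept", format(x$intercept, digits = 4), "\n")
  print(round(x$coefficients, 4))
  cat("AIC:", format(x$aic, digits = 6), "\n")
  invisible(x)
}

#' Predict from a fitted cascade model
#'
#' @param object A `ppm_model`.
#' @param newdata Data frame containing the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions (not clipped).
#' @export
predict.ppm_model <- function(object, newdata, ...) {
  missing <- setdiff(object$predictors, names(newdata))
  check_that(length(missing) == 0, "newdata is missing predictor column(s): ",
             paste(missing, collapse = ", "))
  x <- as.matrix(newdata[, object$predictors, drop = FALSE])
  as.numeric(object$intercept + x %*% object$coefficients)
}

# Wrap an lm fit over the given predictors into a ppm_model, dropping
# aliased (rank-deficient) columns with a warning.
wrap_lm <- function(fit, model_id, design) {
  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased) > 0) {
    warning(model_id, ": dropping aliased column(s) ",
            paste(gsub("`", "", aliased), collapse = ", "), call. = FALSE)
    cf <- cf[!is.na(cf)]
  }
  has_int <- "(Intercept)" %in% names(cf)
  intercept <- if (has_int) unname(cf["(Intercept)"]) else 0
  beta <- cf[setdiff(names(cf), "(Intercept)")]
  names(beta) <- gsub("`", "", names(beta))
  n <- nrow(design)
  rss <- sum(stats::residuals(fit)^2)
  new_ppm_model(model_id, intercept, beta,
                sigma = sqrt(rss / max(1, n - length(cf))),
                aic = ls_aic(n, rss, length(cf)), fit = fit)
}

#' M1: ordinary least squares on applicable crop extents
#'
#' The base model relating the calibration response (kg of one substance
#' in one class per region) linearly to the areas of the crop groups the
#' substance applies to.
#'
#' @param design A `ppm_design` from [assemble_design()].
#' @param predictors Predictor names (default: the design's crop
#'   predictors).
#' @return A `ppm_model`.
#' @export
fit_m1 <- function(design, predictors = attr(design, "crop_predictors")) {
  check_that(nrow(design) > length(predictors) + 1,
             "need more rows (", nrow(design), ") than predictors + 1 (",
             length(predictors) + 1, ")")
  fit <- stats::lm(predictor_formula(predictors), data = design)
  wrap_lm(fit, "M1", design)
}

#' Stepwise AIC selection from a full linear model
#'
#' Bidirectional stepwise selection starting from the full model over the
#' given predictors, minimizing AIC = n ln(RSS/n) + 2(k+1).  The returned
#' model's AIC is never above the full model's.
#'
#' @param design A `ppm_design`.
#' @param scope `"crop"` (the M2 reduction), `"climate"` or `"all"`:
#'   which predictor set the selection runs over.
#' @param model_id Label for the returned model.
#' @return A `ppm_model`.
#' @export
select_stepaic <- function(design, scope = c("crop", "climate", "all"),
                           model_id = "M2") {
  scope <- match.arg(scope)
  predictors <- switch(scope,
                       crop = attr(design, "crop_predictors"),
                       climate = attr(design, "climate_predictors"),
                       all = design_predictors(design))
  full <- stats::lm(predictor_formula(predictors), data = design)
  if (essentially_perfect(full, design$y)) {
    return(wrap_lm(full, model_id, design))
  }
  red <- stats::step(full, direction = "both", trace = 0)
  wrap_lm(red, model_id, design)
}

#' M3: country-augmented model and country-specificity verdict
#'
#' Adds the country label as a categorical block to a base model's
#' predictors.  The verdict `country_specific` is true when the country
#' terms improve AIC by more than `delta_aic`, meaning use patterns differ
#' systematically between countries and extrapolation beyond them is
#' suspect.  M3 is flagged non-extrapolable and is never used for
#' prediction.
#'
#' @param design A `ppm_design` with a `country` column.
#' @param base A fitted base `ppm_model` (M1 or M2).
#' @param delta_aic Evidence margin on the AIC scale (default 2).
#' @return A `ppm_model` with flag `country_specific` set; for a
#'   single-country design the verdict is `NA` and a message is logged.
#' @export
fit_m3 <- function(design, base, delta_aic = 2) {
  if (length(unique(design$country)) < 2) {
    message("M3: single-country design, country-specificity undefined")
    m <- base
    m$model_id <- "M3"
    m$flags$non_extrapolable <- TRUE
    m$flags$country_specific <- NA
    return(m)
  }
  predictors <- base$predictors
  rhs <- paste(c(sprintf("`%s`", predictors), "factor(country)"),
               collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = design)
  m <- wrap_lm(fit, "M3", design)
  m$flags$non_extrapolable <- TRUE
  m$flags$country_specific <- m$aic < base$aic - delta_aic
  m
}

#' M4: climate-augmented model
#'
#' Adds climate features to the base model's crop terms.  Crop terms are
#' protected; climate candidates enter by stepwise AIC selection and at
#' most `cap` climate terms are retained (the least AIC-costly terms are
#' removed first when the selection exceeds the cap).
#'
#' @param design A `ppm_design` whose climate predictors are the candidate
#'   set.
#' @param base Fitted base `ppm_model` supplying the protected crop terms.
#' @param cap Maximum number of retained climate terms (default 4).
#' @return A `ppm_model`.
#' @export
fit_m4 <- function(design, base, cap = 4) {
  crop <- intersect(base$predictors, attr(design, "crop_predictors"))
  climate <- attr(design, "climate_predictors")
  if (length(climate) == 0) {
    m <- base
    m$model_id <- "M4"
    return(m)
  }
  lower <- stats::lm(predictor_formula(crop), data = design)
  if (essentially_perfect(lower, design$y)) {
    # crop terms already explain everything; climate can only cost AIC
    fit <- stats::lm(predictor_formula(crop), data = design)
    return(wrap_lm(fit, "M4", design))
  }
  upper_f <- predictor_formula(c(crop, climate))
  sel <- stats::step(lower, scope = list(lower = stats::formula(lower),
                                         upper = upper_f),
                     direction = "both", trace = 0)
  kept <- gsub("`", "", attr(stats::terms(sel), "term.labels"))
  kept_climate <- intersect(kept, climate)
  while (length(kept_climate) > cap) {
    # drop the climate term whose removal costs least AIC
    aics <- vapply(kept_climate, function(f) {
      cand <- c(crop, setdiff(kept_climate, f))
      fit <- stats::lm(predictor_formula(cand), data = design)
      ls_aic(nrow(design), sum(stats::residuals(fit)^2),
             length(cand) + 1)
    }, numeric(1))
    kept_climate <- setdiff(kept_climate, names(which.min(aics)))
  }
  fit <- stats::lm(predictor_formula(c(crop, kept_climate)), data = design)
  wrap_lm(fit, "M4", design)
}

#' M5: Huber robust regression
#'
#' Refits the model by Huber M-estimation (iteratively reweighted least
#' squares, tuning constant 1.345, MAD scale estimate) to reduce the
#' influence of outlying regions.
#'
#' @param design A `ppm_design`.
#' @param predictors Predictor names (default: all design predictors of
#'   the preferred model should be passed by the caller).
#' @param maxit Iteration cap; non-convergence is an error.
#' @return A `ppm_model` carrying the IRLS weights in `fit$w`.
#' @export
fit_m5 <- function(design, predictors = design_predictors(design),
                   maxit = 200) {
  ols <- stats::lm(predictor_formula(predictors), data = design)
  if (essentially_perfect(ols, design$y)) {
    # no residual scale to reweight against: Huber IRLS degenerates to OLS
    m <- wrap_lm(ols, "M5", design)
    return(m)
  }
  fit <- MASS::rlm(predictor_formula(predictors), data = design,
                   psi = MASS::psi.huber, k = 1.345, scale.est = "MAD",
                   maxit = maxit)
  check_that(isTRUE(fit$converged),
             "M5 (Huber IRLS) did not converge within ", maxit,
             " iterations")
  m <- wrap_lm(fit, "M5", design)
  m$sigma <- fit$s
  m
}

#' M6: non-negative least squares through the origin
#'
#' Least squares under the physical constraints that no predictor can have
#' a negative coefficient (area cannot remove pesticide) and that the
#' intercept is suppressed (zero agricultural area implies zero
#' application).  Solved as a non-negative least-squares problem; a
#' configuration with a penalized free non-negative intercept is available.
#'
#' @param design A `ppm_design`.
#' @param predictors Predictor names.
#' @param intercept `"none"` (default, through-origin) or `"penalized"`
#'   (non-negative intercept shrunk towards zero).
#' @param intercept_penalty Ridge weight on the penalized intercept.
#' @return A `ppm_model`.
#' @export
fit_m6 <- function(design, predictors = design_predictors(design),
                   intercept = c("none", "penalized"),
                   intercept_penalty = 1) {
  intercept <- match.arg(intercept)
  x <- as.matrix(design[, predictors, drop = FALSE])
  y <- design$y
  if (intercept == "penalized") {
    xm <- cbind(`(Intercept)` = 1, x)
    # augmented row shrinks the intercept towards zero
    xa <- rbind(xm, c(sqrt(intercept_penalty), rep(0, ncol(x))))
    sol <- pracma::lsqnonneg(xa, c(y, 0))
    beta0 <- sol$x[1]
    beta <- stats::setNames(sol$x[-1], predictors)
  } else {
    sol <- pracma::lsqnonneg(x, y)
    beta0 <- 0
    beta <- stats::setNames(sol$x, predictors)
  }
  resid <- y - beta0 - as.numeric(x %*% beta)
  rss <- sum(resid^2)
  edf <- sum(beta > 0) + (intercept == "penalized")
  n <- nrow(design)
  new_ppm_model("M6", beta0, beta,
                sigma = sqrt(rss / max(1, n - edf)),
                aic = ls_aic(n, rss, edf))
}

#' Eligibility filter: substances used widely enough to model
#'
#' A substance is eligible when it has strictly positive reported use in
#' at least `min_countries` distinct reporting countries (default 4 of the
#' 8 reference countries).
#'
#' @param reported Reported-use data frame (`country`, `substance_id`,
#'   `kg`).
#' @param substances Candidate substance ids (default: all reported).
#' @param min_countries Minimum number of distinct countries with positive
#'   use.
#' @return Character vector of eligible substance ids.
#' @export
eligibility_filter <- function(reported,
                               substances = unique(reported$substance_id),
                               min_countries = 4) {
  pos <- reported[reported$kg > 0, c("country", "substance_id")]
  counts <- tapply(pos$country, pos$substance_id,
                   function(x) length(unique(x)))
  eligible <- names(counts)[counts >= min_countries]
  intersect(substances, eligible)
}

#' Flag influential / outlying calibration regions
#'
#' A region is flagged when its Cook's distance under the climate model
#' exceeds `cooks_multiplier / n`, or when the climate and robust models
#' disagree on its prediction by more than one residual standard deviation
#' of the climate model.  Flags are reported; rows are never deleted.
#'
#' @param design A `ppm_design`.
#' @param m4,m5 Fitted `ppm_model`s on the same rows (climate-augmented
#'   and robust).
#' @param cooks_multiplier Numerator of the Cook's-distance threshold.
#' @return Character vector of flagged region ids (possibly empty).
#' @export
detect_outliers <- function(design, m4, m5, cooks_multiplier = 4) {
  n <- nrow(design)
  scale_y <- mean(abs(design$y)) + .Machine$double.eps
  # a numerically perfect fit has no meaningful outlier statistics
  if (m4$sigma < 1e-8 * scale_y) return(character())
  flags <- rep(FALSE, n)
  if (!is.null(m4$fit)) {
    cd <- stats::cooks.distance(m4$fit)
    flags <- flags | (is.finite(cd) & cd > cooks_multiplier / n)
  }
  p4 <- predict(m4, design)
  p5 <- predict(m5, design)
  sd_resid <- stats::sd(design$y - p4)
  flags <- flags | (abs(p4 - p5) > sd_resid)
  design$region_id[flags]
}

#' Cascade policy configuration
#'
#' All decision thresholds of the model cascade in one place.
#'
#' @param min_countries Eligibility minimum (countries with positive use).
#' @param delta_aic Country-specificity AIC margin.
#' @param climate_cap Maximum retained climate terms in M4.
#' @param cooks_multiplier Cook's-distance threshold numerator.
#' @param nse_gate Cross-validated NSE below/at which a model is rejected.
#' @param intercept_tol Intercept tolerance as a fraction of mean |y|;
#'   larger intercepts route the decision to M6.
#' @param neg_tol Absolute tolerance before a coefficient counts as
#'   negative.
#' @param cv_k,cv_reps,cv_seed Fold count, repetitions and seed of the
#'   cascade-internal cross-validation gate.
#' @return Named list of policy settings.
#' @export
cascade_policy <- function(min_countries = 4, delta_aic = 2,
                           climate_cap = 4, cooks_multiplier = 4,
                           nse_gate = 0, intercept_tol = 0.1,
                           neg_tol = 1e-8, cv_k = 10, cv_reps = 20,
                           cv_seed = 1L) {
  as.list(environment())
}

model_gate_ok <- function(model, design, policy) {
  !any(model$coefficients < -policy$neg_tol) &&
    abs(model$intercept) <= policy$intercept_tol * mean(abs(design$y))
}

# Refit recipe for cross-validation: same model form, same predictors,
# re-estimated coefficients.
model_recipe <- function(model) {
  predictors <- model$predictors
  switch(model$model_id,
         M5 = function(d) fit_m5(d, predictors),
         M6 = function(d) fit_m6(d, predictors),
         function(d) wrap_lm(stats::lm(predictor_formula(predictors),
                                       data = d),
                             model$model_id, d))
}

cv_nse <- function(design, model, policy) {
  k <- min(policy$cv_k, nrow(design))
  rep_cv <- repeated_kfold(design, model_recipe(model), k = k,
                           repetitions = policy$cv_reps,
                           seed = policy$cv_seed)
  mean(rep_cv$summary$NSE, na.rm = TRUE)
}

#' Run the model cascade for one substance x land-cover class
#'
#' Applies the deterministic decision policy: the base model is the
#' stepwise-reduced M2 for arable land (the only class with a large crop
#' predictor set) and M1 elsewhere; M3 is fitted only to diagnose
#' country-specific use patterns; M4 adds climate terms.  For non-arable
#' classes a clean M4 (no negative coefficients, acceptable intercept,
#' positive cross-validated NSE) closes the sequence.  Otherwise the
#' robust M5 is fitted, regions where M4 and M5 disagree are flagged as
#' outliers and M5 is preferred when any are flagged; a preferred model
#' with negative coefficients or an excessive intercept is replaced by the
#' constrained M6.  A final model whose cross-validated NSE does not
#' exceed the gate is excluded from extrapolation.
#'
#' @param design A `ppm_design` (or `ppm_unmodellable`).
#' @param policy A [cascade_policy()].
#' @return A `cascade_decision`: list with `substance_id`, `landcover`,
#'   `model_id` (or `"excluded"`), `reason`, `country_specific`,
#'   `cv_nse`, `outliers`, `model` (the final `ppm_model` or `NULL`), and
#'   `models` (all fitted stages, for audit).
#' @export
run_cascade <- function(design, policy = cascade_policy()) {
  sub <- attr(design, "substance_id")
  lcc <- attr(design, "landcover")
  decision <- function(model_id, reason, model = NULL, models = list(),
                       country_specific = NA, cv = NA_real_,
                       outliers = character()) {
    structure(list(substance_id = sub, landcover = lcc,
                   model_id = model_id, reason = reason,
                   country_specific = country_specific, cv_nse = cv,
                   outliers = outliers, model = model, models = models),
              class = "cascade_decision")
  }
  if (inherits(design, "ppm_unmodellable")) {
    return(decision("excluded", "ineligible"))
  }
  n_pred <- length(design_predictors(design))
  if (nrow(design) <= n_pred + 1) {
    return(decision("excluded", "ineligible"))
  }
  arable <- identical(lcc, "arable land")
  base <- if (arable) select_stepaic(design, "crop", "M2") else
    fit_m1(design)
  m3 <- fit_m3(design, base, policy$delta_aic)
  m4 <- fit_m4(design, base, policy$climate_cap)
  models <- list(base = base, M3 = m3, M4 = m4)
  outliers <- character()

  preferred <- NULL
  reason <- NULL
  if (!arable && model_gate_ok(m4, design, policy) &&
      cv_nse(design, m4, policy) > policy$nse_gate) {
    preferred <- m4
    reason <- if (length(setdiff(m4$predictors, base$predictors)) == 0)
      "accepted_base" else "accepted_M4"
  } else {
    m5 <- fit_m5(design, m4$predictors)
    models$M5 <- m5
    outliers <- detect_outliers(design, m4, m5, policy$cooks_multiplier)
    if (length(outliers) > 0) {
      preferred <- m5
      reason <- "outliers_to_M5"
    } else {
      preferred <- m4
      reason <- if (length(setdiff(m4$predictors, base$predictors)) == 0)
        "accepted_base" else "accepted_M4"
    }
  }
  preferred$flags$influential_outliers <- outliers
  if (!model_gate_ok(preferred, design, policy)) {
    preferred <- fit_m6(design, preferred$predictors)
    preferred$flags$influential_outliers <- outliers
    reason <- "negative_coefs_to_M6"
  }
  models$final <- preferred
  cv <- cv_nse(design, preferred, policy)
  cs <- m3$flags$country_specific
  if (!is.na(cv) && cv <= policy$nse_gate) {
    reason_out <- if (isTRUE(cs)) "country_specific_only" else "cv_fail"
    return(decision("excluded", reason_out, models = models,
                    country_specific = cs, cv = cv, outliers = outliers))
  }
  decision(preferred$model_id, reason, model = preferred, models = models,
           country_specific = cs, cv = cv, outliers = outliers)
}

#' @export
print.cascade_decision <- function(x, ...) {
  cat(x$substance_id, "/", x$landcover, "->", x$model_id,
      sprintf("(%s; CV NSE %.3f)\n", x$reason, x$cv_nse))
  invisible(x)
}
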