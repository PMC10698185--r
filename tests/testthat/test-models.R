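test_that("eligibility requires positive use in at least 4 distinct countries", {
  mk <- function(s, countries) data.frame(country = countries, scope = countries,
                                          substance_id = s, kg = 1)
  rep_use <- rbind(mk("A", sprintf("CN%02d", 1:4)),
                   mk("B", sprintf("CN%02d", 1:3)),
                   mk("C", sprintf("CN%02d", 1:8)),
                   data.frame(country = "CN04", scope = "CN04",
                              substance_id = "B", kg = 0))  # zero != used
  expect_setequal(eligibility_filter(rep_use), c("A", "C"))
  expect_setequal(eligibility_filter(rep_use, min_countries = 3),
                  c("A", "B", "C"))
})

test_that("M1 recovers exact linear data and matches the normal-equation oracle", {
  d <- make_design(30, c(crop1 = 2), seed = 1)
  m <- fit_m1(d)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-8)
  expect_equal(m$intercept, 0, tolerance = 1e-8)

  # residual orthogonality (normal equations) on noisy data
  dn <- make_design(60, c(crop1 = 2, crop2 = 0.5), sigma = 0.3, seed = 2)
  mn <- fit_m1(dn)
  res <- dn$y - predict(mn, dn)
  x <- as.matrix(dn[, c("crop1", "crop2")])
  expect_lt(max(abs(crossprod(cbind(1, x), res))) /
              max(abs(crossprod(x, dn$y))), 1e-8)

  # pseudo-inverse oracle on a small 5x2 design
  d5 <- make_design(5, c(crop1 = 1, crop2 = 3), sigma = 0.2, seed = 3)
  m5 <- fit_m1(d5)
  oracle <- ols_oracle(d5[, c("crop1", "crop2")], d5$y)
  expect_equal(m5$intercept, unname(oracle[1]), tolerance = 1e-8)
  expect_equal(unname(m5$coefficients), unname(oracle[-1]),
               tolerance = 1e-8)

  # y independent of predictors: slope near zero
  dind <- make_design(200, c(crop1 = 0), seed = 4)
  dind$y <- rnorm(200)
  mi <- fit_m1(dind)
  expect_lt(abs(mi$coefficients[["crop1"]]) * sd(dind$crop1) / sd(dind$y),
            0.2)
})

test_that("stepwise AIC keeps true predictors, never worsens AIC, and matches best-subset", {
  beta <- c(crop1 = 2, crop2 = 0, crop3 = 0, crop4 = 0, crop5 = 0,
            crop6 = 0)
  d <- make_design(200, beta, seed = 5)
  d$y <- d$y + rnorm(200, sd = 50)
  m2 <- select_stepaic(d, "crop")
  expect_true("crop1" %in% m2$predictors)

  full <- fit_m1(d)
  expect_lte(m2$aic, full$aic)

  # exhaustive best-subset oracle agrees for p <= 6
  oracle <- best_subset_aic_oracle(d, names(beta))
  expect_setequal(m2$predictors, oracle$set)
  expect_equal(m2$aic, oracle$aic, tolerance = 1e-8)

  # pure-noise predictors: still never above the full model's AIC
  dn <- make_design(80, c(crop1 = 0, crop2 = 0, crop3 = 0), seed = 6)
  dn$y <- rnorm(80)
  mn <- select_stepaic(dn, "crop")
  expect_lte(mn$aic, fit_m1(dn)$aic)
})

test_that("M3 diagnoses country-specific use and is barred from extrapolation", {
  d <- make_design(160, c(crop1 = 2), sigma = 0.1, seed = 7,
                   n_countries = 4)
  base <- fit_m1(d)

  # inject per-country intercept shifts
  shift <- c(CN01 = 0, CN02 = 3000, CN03 = -2000, CN04 = 5000)
  ds <- d
  ds$y <- ds$y + shift[ds$country]
  m3 <- fit_m3(ds, fit_m1(ds))
  expect_true(m3$flags$country_specific)
  expect_true(m3$flags$non_extrapolable)

  # identical process across countries: no country effect at the margin
  m3n <- fit_m3(d, base)
  expect_false(m3n$flags$country_specific)

  # extrapolation refusal
  fx <- get_fx()
  ptab <- build_prediction_table(fx$regions, fx$climate_features)
  expect_error(extrapolate(m3, ptab), "never used for extrapolation")
})

test_that("M4 retains a simulated climate effect, protects crop terms, and honours the cap", {
  set.seed(800)
  n <- 150
  clim <- data.frame(temp_f = rnorm(n), prec_f = rnorm(n),
                     spare1 = rnorm(n), spare2 = rnorm(n),
                     spare3 = rnorm(n), spare4 = rnorm(n),
                     spare5 = rnorm(n))
  d <- make_design(n, c(crop1 = 2), seed = 8, climate = clim)
  d$y <- d$y + 4000 * d$temp_f + rnorm(n, sd = 100)
  base <- fit_m1(d)
  m4 <- fit_m4(d, base)
  expect_true("temp_f" %in% m4$predictors)
  expect_true("crop1" %in% m4$predictors)  # crop term protected

  # cap enforced even when more features would reduce AIC
  d2 <- d
  d2$y <- d2$y + 3000 * d2$prec_f + 2500 * d2$spare1 + 2000 * d2$spare2 +
    1500 * d2$spare3 + 1000 * d2$spare4
  m4c <- fit_m4(d2, fit_m1(d2), cap = 4)
  n_climate <- length(intersect(m4c$predictors, names(clim)))
  expect_lte(n_climate, 4)
  expect_true("crop1" %in% m4c$predictors)
})

test_that("M5 equals OLS on clean data, resists outliers, and keeps Huber weights in (0,1]", {
  d <- make_design(60, c(crop1 = 2), seed = 9)
  d$y <- d$y + rnorm(60, sd = 10)
  m1 <- fit_m1(d)
  m5 <- fit_m5(d, "crop1")
  expect_equal(m5$coefficients, m1$coefficients, tolerance = 1e-2)

  # one gross outlier: robust slope stays closer to truth than OLS
  dd <- d
  dd$y[5] <- dd$y[5] * 100
  m1o <- fit_m1(dd)
  m5o <- fit_m5(dd, "crop1")
  expect_lt(abs(m5o$coefficients[["crop1"]] - 2),
            abs(m1o$coefficients[["crop1"]] - 2))
  w <- m5o$fit$w
  expect_true(all(w > 0 & w <= 1))
  expect_lt(w[5], 1)
})

test_that("M6 solves constrained least squares: oracle match, KKT, never-negative", {
  # interior solution: exact positive fit recovered
  d <- make_design(30, c(crop1 = 2), seed = 10)
  m6 <- fit_m6(d, "crop1")
  expect_equal(unname(m6$coefficients), 2, tolerance = 1e-8)
  expect_equal(m6$intercept, 0)

  # negatively related predictor pinned at zero
  set.seed(11)
  dneg <- make_design(40, c(crop1 = 2, crop2 = 1), seed = 11)
  dneg$y <- 2 * dneg$crop1 - 1 * dneg$crop2 + rnorm(40, sd = 5)
  m6n <- fit_m6(dneg, c("crop1", "crop2"))
  expect_equal(m6n$coefficients[["crop2"]], 0)
  expect_true(all(m6n$coefficients >= 0))

  # QP oracle on 6x3 designs + KKT conditions
  for (seed in 1:5) {
    set.seed(seed + 100)
    x <- matrix(rlnorm(6 * 3, 3, 1), 6, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- x %*% c(1.5, -0.5, 0.2) + rnorm(6)
    dd <- structure(data.frame(region_id = as.character(1:6),
                               country = "CN01", y = as.numeric(y), x),
                    crop_predictors = c("a", "b", "c"),
                    climate_predictors = character(),
                    substance_id = "SX", landcover = "arable land",
                    class = c("ppm_design", "data.frame"))
    m <- fit_m6(dd, c("a", "b", "c"))
    oracle <- nnls_oracle(x, y)
    expect_equal(unname(m$coefficients), unname(oracle), tolerance = 1e-6)
    # KKT: zero gradient on the active support, non-negative elsewhere
    g <- -2 * as.numeric(t(x) %*% (y - x %*% m$coefficients))
    expect_lt(max(abs(g[m$coefficients > 1e-10])) /
                (1 + max(abs(g))), 1e-6)
    expect_true(all(g[m$coefficients <= 1e-10] > -1e-6 * (1 + max(abs(g)))))
    # constrained residual norm is never below the unconstrained one
    ols_res <- sum(lm.fit(x, y)$residuals^2)
    expect_gte(sum((y - x %*% m$coefficients)^2), ols_res - 1e-8)
  }
})

test_that("outlier detection flags injected anomalies and stays quiet on clean data", {
  set.seed(1200)
  n <- 80
  clim <- data.frame(temp_f = rnorm(n))
  d <- make_design(n, c(crop1 = 2), seed = 12, climate = clim)
  d$y <- d$y + rnorm(n, sd = mean(d$y) * 0.05)
  base <- fit_m1(d)
  m4 <- fit_m4(d, base)
  m5 <- fit_m5(d, m4$predictors)
  flags_clean <- detect_outliers(d, m4, m5)
  # matches an independently coded version of the flagging rule ...
  cd <- stats::cooks.distance(m4$fit)
  disagree <- abs(predict(m4, d) - predict(m5, d)) >
    stats::sd(d$y - predict(m4, d))
  expect_setequal(flags_clean, d$region_id[cd > 4 / n | disagree])
  # ... and clean data only ever yields a handful of borderline flags
  expect_lt(length(flags_clean), 0.1 * n)

  dd <- d
  dd$y[7] <- dd$y[7] * 100
  m4o <- fit_m4(dd, fit_m1(dd))
  m5o <- fit_m5(dd, m4o$predictors)
  flagged <- detect_outliers(dd, m4o, m5o)
  expect_true(dd$region_id[7] %in% flagged)
  expect_true(all(flagged %in% dd$region_id))
})

test_that("the cascade emits one decision per dataset with a coherent reason code", {
  policy <- cascade_policy(cv_reps = 5)

  # clean non-arable data: accepted with positive coefficients
  d <- make_design(60, c(W1000 = 1.8), sigma = 0.1, seed = 13,
                   landcover = "vineyards")
  dec <- run_cascade(d, policy)
  expect_true(dec$reason %in% c("accepted_base", "accepted_M4"))
  expect_true(all(dec$model$coefficients >= 0))
  expect_gt(dec$cv_nse, 0)

  # arable data with injected outliers: robust model preferred
  da <- make_design(80, c(C0000 = 1.5, G0000 = 0.8), sigma = 0.05,
                    seed = 14, landcover = "arable land")
  da$y[c(3, 11)] <- da$y[c(3, 11)] * 60
  deca <- run_cascade(da, policy)
  expect_equal(deca$reason, "outliers_to_M5")
  expect_equal(deca$model_id, "M5")

  # negative fitted slope: routed to the constrained M6
  set.seed(15)
  dneg <- make_design(70, c(C0000 = 2, G0000 = 1), seed = 15,
                      landcover = "arable land")
  dneg$y <- pmax(0, 2 * dneg$C0000 - 1.2 * dneg$G0000 +
                   rnorm(70, sd = 50))
  decn <- run_cascade(dneg, policy)
  expect_equal(decn$model_id, "M6")
  expect_equal(decn$reason, "negative_coefs_to_M6")
  expect_true(all(decn$model$coefficients >= 0))

  # unmodellable input still terminates with a decision
  um <- structure(list(substance_id = "SX", landcover = "arable land",
                       reason = "no calibration rows"),
                  class = "ppm_unmodellable")
  decu <- run_cascade(um, policy)
  expect_equal(decu$model_id, "excluded")
  expect_equal(decu$reason, "ineligible")
})

test_that("dose coefficients are recovered exactly without noise and improve with n", {
  # noise-free: every model variant recovers the dose
  d <- make_design(50, c(C0000 = 1.5, G0000 = 0.8), seed = 16)
  for (fit in list(fit_m1(d), select_stepaic(d, "crop"),
                   fit_m5(d, c("C0000", "G0000")),
                   fit_m6(d, c("C0000", "G0000")))) {
    expect_equal(unname(fit$coefficients[c("C0000", "G0000")]),
                 c(1.5, 0.8), tolerance = 1e-6)
  }
})

test_that("category weight shares flag commonly used substances without policy effect", {
  rep_use <- data.frame(country = "CN01", scope = "CN01",
                        substance_id = c("A", "B", "C"),
                        kg = c(990, 10, 500))
  cat_tab <- data.frame(substance_id = c("A", "B", "C"),
                        category = c("Herbicide", "Herbicide", "Fungicide"))
  sh <- category_weight_shares(rep_use, cat_tab)
  expect_equal(sh$share[sh$substance_id == "A"], 0.99)
  expect_equal(sh$share[sh$substance_id == "B"], 0.01)
  expect_equal(sh$share[sh$substance_id == "C"], 1)
  expect_equal(sh$major, c(TRUE, FALSE, TRUE))  # 1% boundary is exclusive

  audit <- get_calibration()$audit
  expect_true("major_in_category" %in% names(audit))
})
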