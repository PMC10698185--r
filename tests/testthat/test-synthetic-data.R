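test_that("landscape generation is structured, non-negative and reproducible", {
  ls1 <- generate_landscape(2, 3, c("C0000", "W1000"), seed = 42)
  expect_equal(nrow(ls1), 6)
  expect_false(anyDuplicated(ls1$region_id) > 0)
  expect_true(all(startsWith(ls1$region_id, ls1$country)))
  expect_true(all(region_areas(ls1, "total") >= 0))
  expect_true(all(region_areas(ls1, "reported") >= 0))

  ls2 <- generate_landscape(2, 3, c("C0000", "W1000"), seed = 42)
  expect_identical(ls1, ls2)

  # full coverage: reported extents equal totals cell for cell
  expect_equal(region_areas(ls1, "reported"), region_areas(ls1, "total"))
  lsc <- generate_landscape(2, 3, c("C0000", "W1000"), seed = 42,
                            coverage_fraction = 0.6)
  expect_true(all(region_areas(lsc, "reported") <=
                    region_areas(lsc, "total")))

  expect_error(generate_landscape(0, 3, "C0000"), "positive integer")
  expect_error(generate_landscape(2, 3, c("C0000", "C0000")), "unique")
})

test_that("climate generator produces the 24-variable inventory with gradient semantics", {
  ls <- generate_landscape(1, 1, "C0000", seed = 1)
  cells <- generate_climate(ls, cells_per_region = 1, seed = 1)
  expect_equal(nrow(cells), 24)
  expect_setequal(unique(cells$variable),
                  c(sprintf("temp_m%02d", 1:12), sprintf("prec_m%02d", 1:12)))

  ls3 <- generate_landscape(1, 5, "C0000", seed = 1)
  flat <- generate_climate(ls3, cells_per_region = 3, seed = 1,
                           gradient_amplitude = 0, anomaly_sd = 0)
  by_region <- split(flat$value, flat$region_id)
  for (r in by_region) expect_equal(r, by_region[[1]])

  c1 <- generate_climate(ls3, cells_per_region = 3, seed = 9)
  c2 <- generate_climate(ls3, cells_per_region = 3, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1$value[startsWith(c1$variable, "prec")] >= 0))
  expect_error(generate_climate(ls3[0, ], 3), "non-empty")
})

test_that("true use is dose x area in the noise-free case and zero without crops", {
  inv <- default_crop_inventory()
  ls <- generate_landscape(1, 4, inv$crop_code, seed = 5)
  # 10 ha of a single vineyard crop, everything else absent
  ls[, grep("^(total|reported)_", names(ls))] <- 0
  ls$total_W1000 <- 10
  ls$reported_W1000 <- 10
  truth <- synthetic_truth(data.frame(substance_id = "S1",
                                      crop_group = "W1000", dose = 2))
  use <- simulate_true_use(truth, ls, crop_group_map(inv), inventory = inv)
  per_region <- stats::aggregate(kg ~ region_id, use, sum)
  expect_equal(per_region$kg, rep(20, 4))  # 2 kg/ha x 10 ha
  expect_equal(unique(use$landcover), "vineyards")

  # a substance dosed on a group no region grows yields zero
  ls$total_W1000 <- 0
  use0 <- simulate_true_use(truth, ls, crop_group_map(inv), inventory = inv)
  expect_equal(sum(use0$kg), 0)

  bad <- data.frame(substance_id = "S1", crop_group = "NOPE", dose = 1)
  expect_error(simulate_true_use(synthetic_truth(bad), ls,
                                 crop_group_map(inv), inventory = inv),
               "no crop present")
})

test_that("multiplicative log-noise matches the log-normal mean identity", {
  inv <- default_crop_inventory()
  ls <- generate_landscape(1, 1000, "W1000", seed = 11)
  ls$total_W1000 <- 100  # fixed area isolates the noise distribution
  ls$reported_W1000 <- 100
  truth <- synthetic_truth(data.frame(substance_id = "S1",
                                      crop_group = "W1000", dose = 2),
                           noise_sd = 0.3, seed = 11)
  use <- simulate_true_use(truth, ls, crop_group_map(inv), inventory = inv)
  expected_mean <- 2 * 100 * exp(0.3^2 / 2)
  se <- stats::sd(use$kg) / sqrt(nrow(use))
  expect_lt(abs(mean(use$kg) - expected_mean), 3 * se)
})

test_that("reporting aggregates true use by scope and honours omissions", {
  fx <- get_fx()
  # country-level record equals the country's regional sum exactly
  co_level <- fx$reported[fx$reported$country == "CN01", ]
  expect_equal(unique(co_level$scope), "CN01")
  truth_by_cs <- stats::aggregate(
    kg ~ country + substance_id,
    fx$true_use[fx$true_use$country == "CN01", ], sum)
  m <- merge(co_level, truth_by_cs, by = c("country", "substance_id"))
  expect_equal(m$kg.x, m$kg.y, tolerance = 1e-12)

  # mass conservation with no unreported crops, for every reporting country
  rep_tot <- stats::aggregate(kg ~ country, fx$reported, sum)
  true_tot <- stats::aggregate(
    kg ~ country,
    fx$true_use[fx$true_use$country %in% fx$reporting_countries, ], sum)
  m2 <- merge(rep_tot, true_tot, by = "country")
  expect_equal(m2$kg.x, m2$kg.y)

  # unreported crops are removed before summation
  scheme2 <- reporting_scheme(
    resolution = fx$scheme$resolution,
    unreported_crops = list(CN01 = c("C1100", "C1200")))
  rep2 <- simulate_reporting(fx$true_use, scheme2, fx$regions)
  withheld <- sum(fx$true_use$kg[fx$true_use$country == "CN01" &
                                   fx$true_use$crop_code %in%
                                     c("C1100", "C1200")])
  expect_gt(withheld, 0)
  expect_equal(sum(fx$reported$kg[fx$reported$country == "CN01"]) -
                 sum(rep2$kg[rep2$country == "CN01"]),
               withheld, tolerance = 1e-9)

  # non-reporting countries are absent; province scopes stay within country
  expect_false(any(c("CN09", "CN10", "CN11", "CN12") %in%
                     fx$reported$country))
  prov <- fx$reported[fx$reported$country == "CN05", ]
  expect_true(all(startsWith(prov$scope, "CN05_P")))

  # multi-year replicates without noise are identical
  rep_y <- simulate_reporting(fx$true_use, fx$scheme, fx$regions,
                              years = 2011:2013, year_noise_sd = 0)
  by_year <- split(rep_y$kg, rep_y$year)
  expect_equal(by_year[["2011"]], by_year[["2012"]])
  expect_equal(by_year[["2011"]], by_year[["2013"]])
})

test_that("invalid truth and scheme specifications are rejected", {
  expect_error(synthetic_truth(data.frame(substance_id = "A",
                                          crop_group = "G", dose = -1)),
               ">= 0")
  expect_error(synthetic_truth(data.frame(substance_id = "A",
                                          crop_group = "G", dose = 0)),
               "positive dose")
  expect_error(reporting_scheme(c(CN01 = "parish")), "unknown resolution")
  expect_error(reporting_scheme(c(CN01 = "country"),
                                unreported_crops = list(CN02 = "C1100")),
               "outside the scheme")
})
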