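make_profile <- function(weights, inventory = default_crop_inventory()) {
  groups <- names(weights)
  class_map <- group_landcover_map(inventory)
  structure(list(substance_id = "SX", common_name = "x", category = "Herbicide",
                 chemical_class = "x", CAS = "0-0-0", CIPAC = 0,
                 ID_EUPDB = "x",
                 dose_weights = weights, applicable_groups = groups,
                 applicable_codes = inventory$crop_code[
                   inventory$crop_group %in% groups],
                 landcovers = unique(unname(class_map[groups]))),
            class = "substance_profile")
}

test_that("applicable weight is the dose-weighted applicable area", {
  inv <- default_crop_inventory()
  ls <- generate_landscape(1, 2, inv$crop_code, seed = 3)
  ls[, grep("^(total|reported)_", names(ls))] <- 0
  # 10 ha wheat-like + 5 ha of a second cereal, both in C0000
  ls$reported_C1100 <- c(10, 0)
  ls$reported_C1200 <- c(5, 0)
  ls$reported_W1000 <- c(10, 0)
  ls$reported_F1000 <- c(20, 0)

  uniform <- make_profile(c(C0000 = 1), inv)
  expect_equal(unname(applicable_weight(ls, uniform, "reported", inv)),
               c(15, 0))
  weighted <- make_profile(c(W1000 = 2, F0000 = 1), inv)
  expect_equal(unname(applicable_weight(ls, weighted, "reported", inv)),
               c(2 * 10 + 1 * 20, 0))
  none <- make_profile(c(O1000 = 1), inv)
  expect_equal(unname(applicable_weight(ls, none, "reported", inv)),
               c(0, 0))
})

test_that("disaggregation is proportional, mass-conserving and scope-confined", {
  fx <- get_fx()
  profiles <- fx$profiles
  # proportionality on a two-region scope with known weights
  inv <- fx$inventory
  ls <- generate_landscape(1, 2, inv$crop_code, seed = 8)
  ls[, grep("^(total|reported)_", names(ls))] <- 0
  ls$reported_W1000 <- c(30, 70)
  rep1 <- list(scope = "CN01", substance_id = "S04", kg = 100)
  out <- disaggregate_report(rep1, ls, profiles$S04, "reported", inv)
  expect_equal(out$kg, c(30, 70))

  # conservation at 1e-9 relative for every record of the fixture
  for (i in seq_len(nrow(fx$reported))) {
    r <- fx$reported[i, ]
    d <- disaggregate_report(r, fx$regions, profiles[[r$substance_id]],
                             "reported", inv)
    expect_equal(sum(d$kg), r$kg, tolerance = 1e-9)
  }

  # province scope only reaches that province's regions
  prov_rep <- fx$reported[fx$reported$country == "CN05", ][1, ]
  d <- disaggregate_report(prov_rep, fx$regions,
                           profiles[[prov_rep$substance_id]], "reported",
                           inv)
  expect_true(all(fx$regions$province[
    match(d$region_id, fx$regions$region_id)] == prov_rep$scope))

  # uniform weights: amount 10 over three equal regions
  ls3 <- generate_landscape(1, 3, inv$crop_code, seed = 9)
  ls3[, grep("^(total|reported)_", names(ls3))] <- 0
  ls3$reported_W1000 <- 1
  out3 <- disaggregate_report(list(scope = "CN01", substance_id = "S04",
                                   kg = 10),
                              ls3, profiles$S04, "reported", inv)
  expect_equal(out3$kg, rep(10 / 3, 3))
  expect_equal(sum(out3$kg), 10)

  # all-zero weights spread uniformly with a warning
  ls3$reported_W1000 <- 0
  expect_warning(
    outz <- disaggregate_report(list(scope = "CN01", substance_id = "S04",
                                     kg = 9),
                                ls3, profiles$S04, "reported", inv),
    "all-zero")
  expect_equal(outz$kg, rep(3, 3))

  expect_error(disaggregate_report(list(scope = "XX99", substance_id = "S04",
                                        kg = 1),
                                   ls3, profiles$S04, "reported", inv),
               "no region")
})

test_that("disaggregation is idempotent on region-scoped reports and scale-equivariant", {
  fx <- get_fx()
  reg_rep <- fx$reported[fx$reported$country == "CN07", ][1:5, ]
  for (i in seq_len(nrow(reg_rep))) {
    r <- reg_rep[i, ]
    d <- disaggregate_report(r, fx$regions, fx$profiles[[r$substance_id]],
                             "reported", fx$inventory)
    expect_equal(d$region_id, r$scope)
    expect_equal(d$kg, r$kg)
  }
  r <- fx$reported[1, ]
  d1 <- disaggregate_report(r, fx$regions, fx$profiles[[r$substance_id]],
                            "reported", fx$inventory)
  r2 <- r; r2$kg <- 2 * r$kg
  d2 <- disaggregate_report(r2, fx$regions, fx$profiles[[r$substance_id]],
                            "reported", fx$inventory)
  expect_equal(d2$kg, 2 * d1$kg)
})

test_that("land-cover split follows recommended-dose-weighted class areas", {
  inv <- default_crop_inventory()
  ls <- generate_landscape(1, 1, inv$crop_code, seed = 4)
  ls[, grep("^(total|reported)_", names(ls))] <- 0
  ls$reported_W1000 <- 10
  ls$reported_F1000 <- 20

  # single-class substance: 100% to its class
  vines <- make_profile(c(W1000 = 1.8), inv)
  ru <- data.frame(region_id = ls$region_id, country = "CN01",
                   substance_id = "SX", kg = 50)
  sp <- split_by_landcover(ru, vines, ls, "reported", inv)
  expect_equal(sp$kg[sp$landcover == "vineyards"], 50)
  expect_equal(sum(sp$kg), 50)

  # 2 kg/ha on 10 ha of vines vs 1 kg/ha on 20 ha of fruit -> 50/50
  two <- make_profile(c(W1000 = 2, F0000 = 1), inv)
  sp2 <- split_by_landcover(ru, two, ls, "reported", inv)
  expect_equal(sp2$kg[sp2$landcover == "vineyards"], 25)
  expect_equal(sp2$kg[sp2$landcover == "fruit tree"], 25)

  # a class with zero area in the region receives zero
  ls$reported_F1000 <- 0
  sp3 <- split_by_landcover(ru, two, ls, "reported", inv)
  expect_equal(sp3$kg[sp3$landcover == "fruit tree"], 0)
  expect_equal(sp3$kg[sp3$landcover == "vineyards"], 50)
})

test_that("full calibration table conserves reported mass and matches simulated truth", {
  fx <- get_fx()
  calib <- get_calibration()$calibration
  # per-country conservation through disaggregation + class split
  tab <- stats::aggregate(kg ~ country + substance_id, calib, sum)
  rep_tab <- stats::aggregate(kg ~ country + substance_id, fx$reported, sum)
  m <- merge(tab, rep_tab, by = c("country", "substance_id"))
  expect_equal(m$kg.x, m$kg.y, tolerance = 1e-9)

  # zero-noise + full reporting round-trip: calibration equals true use
  truth <- true_use_by_class(fx$true_use)
  mm <- merge(calib, truth,
              by = c("region_id", "country", "substance_id", "landcover"))
  expect_gt(nrow(mm), 1000)
  expect_equal(mm$kg.x, mm$kg.y, tolerance = 1e-9)
})
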