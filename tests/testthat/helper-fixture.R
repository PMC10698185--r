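# Shared reference fixture, computed once per test run.

.cache <- new.env(parent = emptyenv())

get_fx <- function() {
  if (is.null(.cache$fx)) {
    fx <- reference_fixture()
    fx$climate_features <- summarize_climate(fx$climate_cells)
    fx$retained <- prune_correlated(fx$climate_features, 0.9)
    fx$profiles <- substance_profiles(fx$catalog, fx$doses, fx$inventory)
    .cache$fx <- fx
  }
  .cache$fx
}

# Full calibration of the cascade on the noise-free reference fixture.
get_calibration <- function() {
  if (is.null(.cache$cal)) {
    fx <- get_fx()
    .cache$cal <- calibrate_cascade(
      fx$reported, fx$regions, fx$profiles,
      climate_features = fx$climate_features,
      retained_climate = fx$retained)
  }
  .cache$cal
}

get_predictions <- function() {
  if (is.null(.cache$pred)) {
    fx <- get_fx()
    .cache$pred <- predict_emissions(
      get_calibration()$decisions, fx$regions, fx$climate_features,
      fx$authorizations, fx$catalog)
  }
  .cache$pred
}

# True total use per (region, substance), all classes summed.
get_true_totals <- function() {
  fx <- get_fx()
  tt <- stats::aggregate(kg ~ region_id + substance_id,
                         true_use_by_class(fx$true_use), sum)
  names(tt)[3] <- "true_kg"
  tt
}
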