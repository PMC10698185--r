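#!/usr/bin/env Rscript
# Step 3 -- cross-validate the selected models: repeated 10-fold CV and
# leave-one-country-out CV for every retained substance x class, with the
# five normalized goodness-of-fit metrics.
#
# Reads the outputs of analysis/01_simulate.R and analysis/02_calibrate.R.

suppressMessages(library(pestim))
dir.create("results", showWarnings = FALSE)

regions <- read_regions("results/regions.csv")
reported <- read_reported_use("results/reported_use.csv")
cat_in <- read_catalog("results/catalog.csv")
profiles <- substance_profiles(cat_in$catalog, cat_in$doses)
climate_cells <- utils::read.csv("results/climate_cells.csv")
climate_features <- summarize_climate(climate_cells)
retained <- readLines("results/retained_climate_features.txt")
calibration <- utils::read.csv("results/calibration_table.csv")
decisions <- readRDS("results/decisions.rds")

reporting <- unique(reported$country)
rows <- list()
for (d in decisions) {
  if (identical(d$model_id, "excluded")) next
  design <- assemble_design(calibration, d$substance_id, d$landcover,
                            regions, profiles[[d$substance_id]],
                            climate_features = climate_features,
                            retained_climate = retained,
                            reporting_countries = reporting)
  recipe <- function(dd) {
    switch(d$model_id,
           M5 = fit_m5(dd, d$model$predictors),
           M6 = fit_m6(dd, d$model$predictors),
           fit_m1(dd, d$model$predictors))
  }
  kf <- repeated_kfold(design, recipe, k = 10, repetitions = 20, seed = 1)
  loco <- leave_one_country_out(design, recipe)
  kf_means <- colMeans(kf$summary[, c("SMAPE", "NSE", "NRMSE", "R2",
                                      "NMAE")], na.rm = TRUE)
  loco_means <- colMeans(loco$per_fold[, c("SMAPE", "NSE", "NRMSE", "R2",
                                           "NMAE")], na.rm = TRUE)
  rows[[length(rows) + 1]] <- data.frame(
    substance_id = d$substance_id, landcover = d$landcover,
    model_id = d$model_id,
    t(stats::setNames(kf_means, paste0("kfold_", names(kf_means)))),
    t(stats::setNames(loco_means, paste0("loco_", names(loco_means)))))
}
cv <- do.call(rbind, rows)
utils::write.csv(cv, "results/cv_summary.csv", row.names = FALSE)

cat("Cross-validation of ", nrow(cv), " final models ",
    "(10-fold x 20 repetitions + leave-one-country-out):\n", sep = "")
cat("  median k-fold NSE:  ", round(stats::median(cv$kfold_NSE), 3), "\n",
    sep = "")
cat("  median k-fold SMAPE:", round(stats::median(cv$kfold_SMAPE), 3),
    "\n")
cat("  median country-out NSE:", round(stats::median(cv$loco_NSE), 3),
    "\n")
cat("Per-model table written to results/cv_summary.csv\n")
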