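#!/usr/bin/env Rscript
# Step 2 -- build the predictor set and calibrate the model cascade:
# climate summarization and pruning, crop grouping, disaggregation of the
# reported amounts, and one cascade decision per substance x class.
#
# Reads the tables written by analysis/01_simulate.R.

suppressMessages(library(pestim))
dir.create("results", showWarnings = FALSE)

regions <- read_regions("results/regions.csv")
reported <- read_reported_use("results/reported_use.csv")
cat_in <- read_catalog("results/catalog.csv")
climate_cells <- utils::read.csv("results/climate_cells.csv")
profiles <- substance_profiles(cat_in$catalog, cat_in$doses)

climate_features <- summarize_climate(climate_cells)
retained <- prune_correlated(climate_features, threshold = 0.9)
cat("Climate features: ", ncol(climate_features) - 1, " candidates, ",
    length(retained), " retained after |r| > 0.9 pruning\n", sep = "")
writeLines(retained, "results/retained_climate_features.txt")

cal <- calibrate_cascade(reported, regions, profiles,
                         climate_features = climate_features,
                         retained_climate = retained)
cat("Eligible substances (positive use in >= 4 reporting countries): ",
    length(cal$eligible), " of ", nrow(cat_in$catalog), "\n", sep = "")

utils::write.csv(cal$audit, "results/cascade_audit.csv", row.names = FALSE)
utils::write.csv(cal$calibration, "results/calibration_table.csv",
                 row.names = FALSE)
saveRDS(cal$decisions, "results/decisions.rds")

cat("Cascade decisions by final model and reason:\n")
print(table(cal$audit$model_id, cal$audit$reason))
cat("Audit written to results/cascade_audit.csv\n")
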