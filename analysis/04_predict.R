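#!/usr/bin/env Rscript
# Step 4 -- extrapolate the selected models to every region from total
# crop extents, apply authorization masking, write the emission dataset,
# and compare the estimates with the generator's ground truth.
#
# Reads the outputs of analysis/01_simulate.R and analysis/02_calibrate.R.

suppressMessages(library(pestim))
dir.create("results", showWarnings = FALSE)

regions <- read_regions("results/regions.csv")
cat_in <- read_catalog("results/catalog.csv")
auth <- utils::read.csv("results/authorizations.csv")
climate_cells <- utils::read.csv("results/climate_cells.csv")
climate_features <- summarize_climate(climate_cells)
decisions <- readRDS("results/decisions.rds")
truth <- utils::read.csv("results/true_use.csv")

pe <- predict_emissions(decisions, regions, climate_features, auth,
                        cat_in$catalog)
write_emissions(pe$primary, "results/emissions.csv")
write_emissions(pe$detailed, "results/emissions_detailed.csv")

cat("Emission dataset: ", nrow(pe$primary), " (region x substance) rows; ",
    pe$clipped, " negative prediction(s) clipped, ", pe$masked,
    " masked by authorization\n", sep = "")

# compare against ground truth per (region, substance)
tt <- stats::aggregate(kg ~ region_id + substance_id, truth, sum)
id_map <- stats::setNames(cat_in$catalog$substance_id,
                          cat_in$catalog$common_name)
est <- data.frame(region_id = pe$primary$NUTS3,
                  substance_id = unname(
                    id_map[pe$primary$`Substances common names`]),
                  modeled = pe$primary$KG_TOT)
names(tt)[3] <- "reported"
cmp <- compare_external(est, tt, group_keys = "substance_id")
utils::write.csv(cmp, "results/truth_comparison.csv", row.names = FALSE)

cat("Modeled vs true use per substance (regions pooled):\n")
cat("  modeled/true ratio range: ",
    paste(round(range(cmp$ratio), 4), collapse = " .. "), "\n", sep = "")
cat("  median |log10 deviation|: ",
    signif(stats::median(abs(cmp$median_log_dev)), 3), "\n", sep = "")
cat("  fraction of estimates within one order of magnitude: ",
    round(mean(cmp$frac_within_oom), 4), "\n", sep = "")
cat("Tables written to results/emissions*.csv and ",
    "results/truth_comparison.csv\n", sep = "")
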