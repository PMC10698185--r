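Package: pestim
Title: Regional Estimation of Pesticide Active-Substance Use by
    Disaggregation and Regression Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates regional agricultural emissions (applied quantities)
    of pesticide active substances from coarsely reported national or
    provincial use records.  Reported amounts are disaggregated to small
    (NUTS3-like) regions proportionally to dose-weighted crop areas and
    split across six agricultural land-cover classes; per-substance use is
    then modelled per class with a cascade of six linear-regression
    variants (crop-only, stepwise-AIC-reduced, country-augmented,
    climate-augmented, Huber-robust, and non-negativity-constrained
    through-origin least squares) and extrapolated to all regions from
    total crop extents, with authorization masking.  Includes a synthetic
    landscape, climate and reporting generator with known ground truth,
    repeated k-fold and leave-one-country-out cross-validation with
    SMAPE, NSE, NRMSE, R2 and NMAE metrics, and writers for the published
    CSV schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
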