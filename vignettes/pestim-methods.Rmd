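---
title: "Methods: regional pesticide-use estimation by disaggregation and regression extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional pesticide-use estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestim)
```

## The estimation problem

Use of plant-protection-product active substances (AS) is reported as
kilograms at country, province or (rarely) region scope, over the crops
each country chooses to report on. The quantity of interest is the mass
applied per small region and per agricultural land-cover class (arable
land, fruit tree, grassland, olive groves, vineyards, rice fields), for
*all* regions — including countries that report nothing. `pestim`
estimates it in two movements:

* **downscaling** of the reported amounts to the regions and classes of
  the reporting countries, proportionally to crop areas (a dasymetric
  apportionment that conserves mass), and
* **extrapolation** of the relationship between downscaled use and
  regional predictors (crop-group areas and climate summaries), fitted
  per substance and class, to every region.

The central modelling assumption is linearity on the raw kg scale:
`y = β₀ + β₁x₁ + … + β_p x_p + ε`, where the crop-area coefficients are
interpretable as effective doses (kg/ha). Two further working
assumptions are inherited from the data-generating reality: sales and
use are treated as equivalent, and multi-year reports are averaged into
one representative level, so estimates describe a reference period
rather than a specific year.

## Calibration versus prediction extents

Reported amounts cover only the crops a country reports on, so two area
variants are carried through the pipeline: *reported-coverage* extents
(used to calibrate — the response only contains mass applied on the
covered area) and *total* extents (used to predict — the estimate should
cover all cultivated area). `region_areas()` exposes the switch; the
disaggregation and design-assembly stages default to the reported
variant and `build_prediction_table()` to the total variant.

## Disaggregation

A report of `A` kg with scope `s` is split over the regions `r ∈ s` as
`A · w_r / Σ w_r`, with `w_r = Σ_c d_g(c) · area_r(c)` summing over the
substance's applicable crops `c`, weighted by the relative recommended
dose `d_g` of the crop's group. Within a region, the amount is then
split across land-cover classes proportionally to the same dose-weighted
areas aggregated per class; single-class substances map entirely to
their class. Scopes whose weights are all zero are spread uniformly with
a warning rather than dropped — on sparse synthetic inputs this keeps
mass conservation intact and auditable. Conservation at every step is
tested to 1e-9 relative tolerance.

Dose weights default to uniform within a crop group — the grouping is
built on the assumption that doses are similar for all crops in a group —
and profile-supplied weights override.

## Predictor construction

**Climate.** Each of the 24 monthly variables (12 temperature, 12
precipitation) is summarized per region by minimum, maximum, median,
mean and sample (n−1) standard deviation: 120 candidate features.
Because these statistics are strongly collinear, the set is reduced by
iterative pairwise pruning: while any retained pair has |Pearson r|
above the threshold (default 0.9), the worst pair is located and the
member with the larger mean absolute correlation to the remaining
features is dropped (ties drop the later column, making the result
deterministic in column order). The pruning score is not uniquely pinned
down by the field's verbal descriptions; the mean-absolute-correlation
convention used here is the common one in collinearity filters. Constant
columns are dropped first with a warning, since their correlation is
undefined. Under the default synthetic conditions pruning retains 12
features, giving 16 + 12 = 28 candidate predictors.

**Crops.** The 44-code crop inventory is summed into 16 group predictors
(10 arable-land groups, 2 fruit-tree, and one each for grassland,
olives, vines and rice). Codes outside the grouping are dropped and
logged; grouping conserves total area.

## The model cascade

For every substance × class dataset (rows = regions of the reporting
countries):

* **M1** — OLS on the applicable crop-group areas.
* **M2** — stepwise-AIC reduction of M1, with
  `AIC = n·ln(RSS/n) + 2(k+1)`. Only arable land has enough crop
  predictors for the reduction to matter; other classes have one or two,
  so M2 would equal M1 and the base model is M1 there.
* **M3** — base predictors plus the country as a categorical block.
  Evidence margin: the data are called country-specific when M3 improves
  AIC by more than 2 (the standard evidence threshold; no margin is
  prescribed elsewhere). M3 exists only as a diagnostic — extrapolating
  a model with country terms to countries outside the data is
  meaningless, and `extrapolate()` refuses it.
* **M4** — climate features added to the protected crop terms by
  stepwise AIC, capped at 4 retained climate terms (the cap prevents
  overfitting the small calibration sets; when the selection exceeds it,
  the least AIC-costly terms are removed first).
* **M5** — Huber M-estimation (IRLS, tuning constant 1.345, MAD scale,
  at most 200 iterations; non-convergence is an error, and a numerically
  perfect OLS fit short-circuits to OLS since there is no residual scale
  to reweight against).
* **M6** — least squares under β_j ≥ 0 with the intercept fixed at 0.
  "Minimizing the intercept" is realized as suppressing it: applying
  substance on zero agricultural area has no physical reading. A config
  variant keeps a free non-negative intercept shrunk by a ridge penalty
  (`fit_m6(..., intercept = "penalized")`).

**Decision policy.** The branch conditions of the published flowchart
are narrative rather than formal, so the policy here is a deterministic
reconstruction, with every threshold collected in `cascade_policy()`:

1. base = M2 (arable) or M1; fit M3 for the country-specificity flag;
   fit M4.
2. Non-arable datasets accept M4 when it is clean — no negative
   coefficients, intercept within tolerance, cross-validated NSE > 0.
3. Otherwise fit M5 and flag outlying regions: Cook's distance under M4
   above 4/n, or M4/M5 prediction disagreement above one residual sd of
   M4. Any flags prefer M5. Flags are reported, never deleted — the
   published procedure "rectifies" outliers without stating row removal,
   so model preference is the faithful deterministic reading.
4. A preferred model with a negative coefficient, or an intercept larger
   than 10% of mean |y| (`intercept_tol`; no value is prescribed
   elsewhere, and 10% keeps harmless small intercepts while catching
   physically implausible ones), is replaced by M6.
5. Final gate: a model whose cross-validated NSE does not exceed 0 is no
   better than predicting the mean and the dataset is excluded — with
   reason `country_specific_only` when the M3 flag is set (the data are
   modellable only with country effects, hence not transferable), else
   `cv_fail`.

Every eligible dataset terminates in exactly one decision with a reason
code, written to a machine-readable audit table. Eligibility itself
requires strictly positive reported use in at least 4 of the 8 reporting
countries. Expert-judgement overrides admitted by the published
procedure are deliberately out of scope: the policy is fully
deterministic.

Responses are modelled on the raw kg scale throughout, because M6's
non-negativity semantics attach to raw coefficients; logarithmic views
are presentation only.

## Cross-validation and metrics

`repeated_kfold()` shuffles rows into k folds (sizes differing by at
most one) and refits the *final model form* — same variant, same
selected predictors, re-estimated coefficients — on each training set;
the default protocol is 10 folds × 100 repetitions, so each observation
is validated exactly 100 times. `leave_one_country_out()` probes
cross-country transferability: a country's predictions use none of its
rows. The cascade's internal gate uses 10 × 20 (the gate only needs the
sign of NSE; the policy exposes `cv_reps`).

Metrics (all normalized, comparable across substances of very different
magnitude):

* SMAPE on the [0, 2] scale, `mean(2|ŷ−y|/(|y|+|ŷ|))`, 0/0 terms
  counted as 0;
* NSE `1 − Σ(y−ŷ)²/Σ(y−ȳ)²` (0 = as good as the observed mean);
* NRMSE and NMAE normalized by mean(observed) — the normalizer is not
  uniquely specified in common usage, so the convention is recorded in
  every serialized report;
* R² as the squared Pearson correlation of observed and held-out
  predictions (safe under cross-validation; a coefficient-of-
  determination variant is available).

External comparisons (`compare_external()`) report the
modeled-to-reported ratio of group sums, the median and MAD of per-entry
`log10(modeled+1) − log10(reported+1)` deviations (the +1 kg shift keeps
zeros finite), and the fraction of entries within one order of magnitude
(boundary inclusive).

## The synthetic generator

The generator replaces the non-redistributable national inputs with a
study whose ground truth is known, so every pipeline stage is testable:

* **Landscape** — crop areas per region drawn log-normal (median 500 ha,
  log-sd 1.0), heavy-tailed like real agricultural statistics; regions
  nest in provinces (2 regions each) within countries. Reported-coverage
  areas are a configurable fraction of totals (default 1).
* **Climate** — each region's monthly climate departs from a fixed
  continental seasonal cycle by one smooth monthly anomaly (cross-region
  gradient, default amplitude 8 °C, plus independent regional anomalies,
  sd 2 °C) that drives temperature and precipitation jointly (4 mm per
  °C); within-region cells follow a fixed quantile pattern whose scale
  is log-linearly tied to the same anomaly. The five summary statistics
  of one month therefore form one collinear block while months remain
  distinguishable — encoding the redundancy that makes correlation
  pruning of real climate summaries collapse each variable's statistics,
  and giving the pruning stage a well-defined outcome (one feature per
  month).
* **Use** — true use is `dose × total area × exp(climate term) ×
  exp(ε)` with one N(0, noise_sd²) draw per (region, substance):
  multiplicative log-scale noise keeps mass non-negative by
  construction. Catalog dose weights equal the generating doses, the way
  manufacturer recommendations drive apportionment in the real pipeline.
* **Reporting** — per-country resolution (country / province / region),
  optional unreported crops (removed before summation), optional
  non-reporting countries and per-year replicates with independent
  log-normal noise.

The default study ("reference fixture", seed 42) has 12 countries — 8
reporting at mixed resolutions, 4 silent — of 10 regions each, 12
substances spanning all six classes, and no noise, which makes the
end-to-end identity testable: predictions equal simulated truth to
1e-6 relative. An optional per-country dose multiplier exists for
experiments in cross-country heterogeneity but is off by default, since
no magnitude for it is established.

What the generator does *not* emulate: geographic realism (no
geometries or rasters; "provinces" are index blocks), country-specific
crop portfolios, reporting biases other than crop omission, and
structured measurement error. Passing tests therefore demonstrate
correctness of the pipeline's mechanics and estimator behaviour under
the stated generative model, not accuracy on real national data.

## Numerical choices and degenerate inputs

* Stepwise selection, climate selection and Huber reweighting are
  short-circuited on numerically perfect fits (RMSE below 1e-10 of the
  response scale): selection on an exact fit is undefined and IRLS has
  no scale to converge on.
* Rank-deficient designs drop aliased columns with a warning rather
  than failing.
* Outlier statistics are suppressed when the residual sd is below 1e-8
  of the response scale (a perfect fit has no meaningful Cook's
  distances).
* All-zero apportionment weights spread uniformly with a warning;
  zero-cell regions and constant features error or warn explicitly.
* Median uses the midpoint convention for even counts; standard
  deviations are sample (n−1).
* Negative extrapolations are clipped to zero with a counter; masked
  and clipped counts are reported, never silent.
* Exact duplicate reported-use records are a load error: no precedence
  rule is guessed.

## Problem sizes used by the tests

The suite runs the full pipeline on the 120-region reference fixture
(seconds), parameter-recovery checks at 40/80/160 regions with log-noise
sd 0.3 (10 replicate landscapes each), metric-oracle comparisons on
1000 random vector pairs, and exhaustive-enumeration oracles (best
subset, active-set NNLS) on designs small enough to enumerate (≤ 6
predictors, 6-row NNLS designs). These sizes were chosen to keep the
default test run in the low minutes while leaving every statistical
check well-powered.

## Known limitations

* The decision policy is a deterministic reconstruction of a published
  flowchart whose exact branch conditions are narrative; other faithful
  reconstructions exist.
* Climate enters linearly through at most four selected features; the
  generator's log-linear climate modulation is therefore only locally
  matched by the fitted models.
* The candidate climate inventory is fixed at 24 monthly variables × 5
  statistics = 120; annual aggregates are excluded from the expansion.
* Excluded-substance bookkeeping is by reason code only; no attempt is
  made to reproduce any particular published exclusion ledger.
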