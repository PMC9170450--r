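---
title: "Methods: the coupled value-transfer model in wetval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled value-transfer model in wetval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetval)
```

## The model

`wetval` estimates wetland ecosystem-service values by benefit transfer: a
meta-regression calibrated on published valuation cases predicts
per-hectare values for new wetland units. The calibration model couples
three views of a valuation observation —

* **dimension**: which service is valued and by which method, entered as
  0/1 indicators `X_m`;
* **space**: the wetland's position in the land-type × service supply
  matrix, condensed into the aggregate supply score
  `X_d = Σ_j N_ij A_ij` (integer capacity 0–10 times area in hm², summed
  over services);
* **attribute**: continuous covariates — natural descriptors of the wetland
  `X_w` and environmental/socio-economic indices `X_c` of its setting,

in one log-linear equation

$$\ln V = \beta_0 + \beta_w X_w + \beta_c (X_d \cdot X_c) + \beta_m X_m + U,$$

with `V` the unit value in yuan/(hm²·yr) at a common price level and `U`
homoscedastic noise on the ln scale. The log link reflects the strictly
positive, right-skewed distribution of unit values and turns proportional
effects into additive coefficients. Assumptions worth keeping in mind:
observations are treated as independent given covariates (no
spatial-autocorrelation structure), the noise variance is constant on the
ln scale, and the supply score enters only through products with `X_c`.

### Interaction structure

The model couples space and attributes through the product `X_d · X_c`.
The supply score is a scalar per wetland; it multiplies each environmental
covariate element-wise, so each `β_c` coefficient measures how the value
response to that covariate scales with the wetland's service-weighted
size. The supply score sums over all services of the supply matrix by
default (`supply_score(..., per_service = FALSE)`): it quantifies the
wetland's total benefit capacity. A per-service score is available by flag
for users who prefer service-specific coupling.

### Identifiability of the indicator blocks

Plain 0/1 coding of every service and method level is rank-deficient with
an intercept, so `build_design()` drops one reference category per group
(the alphabetically first level). Coefficients for the remaining levels
are ln-scale contrasts against the reference; predictions are invariant to
the choice of reference.

### Standardization and the original scale

Continuous columns (`X_w` and the interactions) are z-scored on the
training set for numerical conditioning. Because standardization is an
affine map, the fit stores the centring constants and reports exact
original-scale coefficients and their covariance alongside the
standardized ones (`coefficients_original`, `se_original`); predictions
apply the training transform, which makes them invariant under affine
rescaling of any covariate.

## Calibration pipeline

1. **CPI adjustment.** Unit values observed in different evaluation base
   years are brought to the base-year price level (default 2013) by the
   index ratio `value × index(base)/index(year)`. A missing year is a hard
   error, not an extrapolation.
2. **OLS fit** by QR decomposition; rank deficiency is reported with the
   names of the collinear columns.
3. **Outlier rejection.** Internally studentized residuals
   `r_i = e_i/(s√(1−h_ii))` are computed once and rows with `|r_i| > 2.5`
   are removed before a single refit. The rule names one pass, not a loop;
   an iterated variant is available behind `iterate = TRUE`. The 2.5
   cut-off corresponds to a ≈1.2% removal rate on clean normal data, which
   the acceptance suite verifies empirically. A numerically perfect fit
   (residual sd below 1e-10 of the response scale) removes nothing —
   studentizing rounding noise would otherwise flag arbitrary rows.
4. **Leave-one-out cross-validation** uses the exact OLS identity
   `e_(i) = e_i/(1−h_ii)`; the test suite proves it against literal
   n-refits to 1e-8. Reported: RMSE of ln-scale LOO errors and the mean
   absolute percentage transfer error on the value scale.
5. **Retransformation.** Back-transforming `exp(lp)` underestimates the
   conditional mean. The default correction is Duan's smearing factor
   `mean(exp(residuals))`, which assumes only i.i.d. errors; the naive
   factor 1 and the normal-theory `exp(σ²/2)` are selectable
   (`retransform = "naive" | "normal"`).

## Service weights (AHP)

Comprehensive service-function weights are derived from reciprocal
pairwise-comparison matrices: per-level weights are the normalized
principal right eigenvector (power iteration, tolerance 1e-12, at most
10 000 iterations — a positive matrix has a simple dominant eigenvalue);
the comprehensive weight of a service is the level-weighted sum over the
beneficiary levels (local, provincial, national, global), renormalized.
Consistency is screened by `CR = CI/RI(n)` with Saaty's random-index table
(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49 for n = 1..10) and
threshold 0.1; both are standard AHP constants and configurable. When no
questionnaire data are available, `reference_service_weights()` supplies a
published ten-service weight set; its printed values sum to 0.9991 (a
rounding artifact we preserve verbatim and renormalize only on request).
Weights computed from a supplied hierarchy always supersede the fixture.

## Direct valuation estimators

Four standard estimators generate case values and can be used standalone:
direct market value `Σ S_i Y_i P_i`; shadow-project cost `Σ X_i`;
the equivalence-factor method `ESV = Σ S_i · VC_i` (per-service form
`ESV_j = Σ S_i · VC_ij`), where the regional adjustment of the standard
unit-value table is implemented as a single multiplicative biomass factor —
the adjustment is described only verbally in the literature this follows,
so the scalar form is a deliberate, flagged simplification; and the
runoff-regulation value `Q_max × C` (shadow engineering). All are
nonnegative, additive over disjoint inputs and homogeneous of degree 1 in
prices/costs, which the property tests exercise under random scaling.

## The synthetic study generator

No public case database accompanies the methodology, so `generate_bundle()`
creates one with known ground truth, emulating the study conditions the
model targets: 62 wetland cases carrying 349 observations (each case at
least one, the remainder multinomially), 6 wetland types, 8 final
services, 4 evaluation methods, base years 1995–2013 with a CPI drifting
2.5%/yr (sd 1%) and normalized to 100 in 2013. Choices a field analyst
would call realistic, made once and documented here:

* **areas** ln-normal with meanlog `log(500)` and sdlog 1 (hm²) — valuation
  cases span small ponds to estuarine complexes over several orders of
  magnitude;
* **covariates**: shape index normal (2, 0.5); GDP and population-density
  indices ln-normal (0, 0.5); the natural block also carries `ln(area)` so
  wetland scale enters `X_w` directly;
* **noise** `σ_log = 0.3`, giving a LOO RMSE near `0.3·√(n/(n−p)) ≈ 0.31`
  under correct specification;
* **truth coefficients**: intercept 6; natural effects 0.30 (ln area) and
  −0.15 (shape); interaction effects ±1–2 × 10⁻⁵ (sized to the supply-score
  scale); service contrasts in ±0.6; method contrasts (0.45, −0.35, 1.00),
  whose extreme pair implies an `e^{1.35} ≈ 3.9`-fold value ratio between
  evaluation methods — the order of disparity practitioners report between
  method families;
* **AHP matrices** built as `a_ij = (w_i/w_j)·exp(ε)`, `ε ~ N(0, 0.05²)`,
  around known composite weights, keeping CR < 0.1 with high probability;
* **outliers** planted by shifting ln-values `+10σ` in a configurable
  fraction of rows, with identities recorded in the truth block;
* observed values are de-adjusted to their nominal year by the inverse CPI
  ratio, so the pipeline's CPI step is genuinely exercised.

What the generator does **not** emulate: real coastal geography and
province effects, spatial autocorrelation between nearby cases, reporting
heterogeneity between source studies, and any real CPI history. Passing
recovery tests therefore demonstrate correctness of the estimation
machinery under the stated model, not robustness to misspecified real
data.

`worked_example()` is the degenerate, fully deterministic bundle (3 types ×
2 services, 12 noise-free observations, supply scores 16/50/70/160 by hand)
used in the README and smoke tests.

## Problem sizes and numerical choices

The test and acceptance suites run the generator at its default size
(n = 349, p = 15) for 200 seeds in the recovery study and 100 seeds in the
outlier study, and a 5000-observation draw for the forward-model noise
check — sizes at which the empirical summaries (coverage of ±3 SE,
mean LOO RMSE, false-removal rate) are stable to well within their
acceptance bands. Other numerical policies: supply-capacity normalization
rounds half-up (`floor(x + 0.5)`) so ties break away from zero and a
maximal raw capacity always maps to 10; the per-service axis is the
default because capacities express relativity within a service;
normalization is idempotent on its own output. Reciprocality of judgment
matrices is enforced to 1e-9; weight vectors renormalize to sum 1 within
1e-9. All stochastic routines take an explicit seed (default 20130101) and
the pipeline writes a provenance block (seed, configuration, its checksum,
package version) sufficient to reproduce outputs byte-for-byte.

## Open design decisions taken

* The printed form of the coupling equation in the methodology literature
  duplicates the natural-block coefficient symbol; we implement the
  standard linear form in which each coefficient group appears once.
* Whether `X_d` should be total or per-service in the interaction is
  ambiguous in prose; we default to the total (it is described as the
  wetland's total benefit quantity) and expose the per-service variant.
* Evaluation-method codes are open: the estimator identifiers of this
  package plus free codes (`travel_cost`, `other`), since the method
  taxonomy is study-specific.
* Missing covariates are an error, never imputed — the model defines no
  missing-data mechanism.
* Monetary units are fixed at yuan/(hm²·yr) for unit values and yuan/yr
  for totals; no currency conversion is attempted.

## Limitations

Totals aggregated over a synthetic inventory are illustrative only — their
absolute scale follows the generator's distributions, not any real wetland
stock. The model inherits the usual value-transfer caveats: transfers are
only as good as the case database's coverage of the target conditions, and
ln-scale homoscedasticity is an approximation to reporting practices that
differ between source studies. Spatial autocorrelation, Bayesian
estimation and GIS raster processing are out of scope.
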