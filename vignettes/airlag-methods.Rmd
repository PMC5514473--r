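---
title: "Methods: distributed-lag quasi-Poisson models for air pollution and hospital admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributed-lag quasi-Poisson models for air pollution and hospital admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airlag)
```

## The analysis model

`airlag` implements the canonical ecological time-series design for
short-term air-pollution epidemiology: daily counts of hospital admissions
$Y_t$ are related to daily city-level pollutant concentrations through a
log-link count regression,

$$
Y_t \sim \text{quasi-Poisson}(\mu_t), \qquad
\log \mu_t \;=\; \alpha \;+\; \sum_{\ell=0}^{7} \beta_\ell\, \mathrm{AP}_{t-\ell}
\;+\; s(t;\, 7\ \mathrm{df/year}) \;+\; s(T_t;\, 4\ \mathrm{df})
\;+\; s(H_t;\, 4\ \mathrm{df}) \;+\; \gamma\, \mathrm{DOW}_t ,
$$

where $\mathrm{AP}$ is one pollutant's daily concentration (CO in mg/m³,
SO₂/NO₂/O₃/PM₂.₅/PM₁₀ in µg/m³), $s(\cdot)$ are natural cubic splines,
$T$ and $H$ are the daily mean temperature and relative humidity, and DOW
is a day-of-week block. Pollutants are modelled one at a time (with an
optional second pollutant as a linear same-day term) to limit
collinearity. Effects are reported as rate ratios per 10 µg/m³ (1 mg/m³
for CO): $\mathrm{RR} = e^{\beta \Delta}$ with a 95% Wald interval
$e^{(\beta \pm 1.959964\,\mathrm{se})\Delta}$.

Key assumptions:

* the exposure–response relation is **linear on the log scale** over the
  observed concentration range;
* confounding is dominated by **shared temporal structure** (season,
  long-term trend, weather, weekly cycles), which the spline and DOW blocks
  absorb — individual-level confounders are out of reach by design;
* counts may be **overdispersed**; the quasi-Poisson dispersion
  $\hat\varphi = \chi^2_{\text{Pearson}}/(n - p)$ rescales the covariance
  without changing the point estimates.

### Lag structures

Three exposure bases cover the usual reporting variants
(`lag_structure()`):

* **single**: one model per lag, containing only $\mathrm{AP}_{t-\ell}$;
* **unconstrained**: all eight lags simultaneously, one free coefficient
  each;
* **constrained**: lag-stratified, with one shared coefficient per stratum.
  The default strata $\{0\}, \{1,2\}, \{3..7\}$ were chosen because a
  lag-stratified basis is the structure that reproduces the characteristic
  repeated-estimate pattern across lags 1–2 and 3–7 seen in published
  constrained distributed-lag tables; the strata are configurable. With
  one stratum per lag the constrained basis is a full-rank
  reparameterization of the unconstrained model and yields identical
  fitted values (this is asserted in the test suite to 1e-8).

In the constrained column block, each column is the *sum* of the exposure
over its stratum's lags, so the coefficient is the shared per-unit log
rate-ratio at every member lag; results are reported at each member lag
with identical values, matching how constrained tables are printed.

### Splines and day-of-week

The time spline's total dimension is `round(df_per_year * span / 365.25)`
(2191 days at 7 df/year gives 42 columns), built on the numeric day index
so calendar gaps after complete-case filtering are respected; knots sit at
equally spaced quantiles and the basis is linear beyond the boundary knots
(`splines::ns` provides the basis; the tests verify the dimension, the
vanishing tail curvature, and the span against a hand-built
truncated-power natural spline). Temperature and humidity enter as
same-day daily means through 4-df natural splines. Degrees of freedom for
either block can be selected over candidates 1..10 by minimizing the
quasi-AIC (`select_df()`; ties go to the smaller df; the default order
fits the time df first, then weather).

Day-of-week is, by default, six indicator columns with Saturday — the
first day of the Iranian week — as reference. Because "day of the week"
adjustments are sometimes operationalised as the time since the last
holiday, a `days_since_holiday` mode (one integer column, requires a
holiday calendar) is provided as a logged configuration switch; the two
conventions are not equivalent and the indicator mode is the default.

### Fitting and model selection

`qp_fit()` is the package's own IRLS implementation: deterministic start
(intercept at $\log(\bar y + 0.5/n)$, other coefficients 0), convergence
when the relative deviance change is below 1e-9 (at most 100 iterations,
with step-halving if an update overshoots), and an error — never a silent
result — on rank deficiency or non-convergence. The point estimates are
Poisson ML (verified against a brute-force generic optimizer and against
`stats::glm` in the tests); quasi-Poisson enters only through
$\hat\varphi$. AIC is not defined under quasi-likelihood, so model
selection uses the quasi-AIC $-2\ell/\hat\varphi + 2p$, with the plain
Poisson AIC available by `use_dispersion = FALSE`. Wald (normal) intervals
use the exact 0.975 quantile 1.959964, which makes the CI-excludes-1 /
p < 0.05 duality exact.

## Missing pollutant data

Monitoring networks lose 20–35% of days per pollutant to instrument
failure. Two strategies are implemented:

* **EM imputation** (`em_impute()`): a 6-dimensional multivariate normal
  over the daily pollutant vector, days independent — the simplest joint
  model. The E-step computes conditional means and covariances of the
  missing coordinates per missingness pattern; the M-step updates the mean
  and covariance; iteration stops when the observed-data log-likelihood
  changes by less than 1e-6 (at most 500 iterations). The log-likelihood is
  non-decreasing by construction and is asserted on every run. Missing
  entries are replaced by conditional means at the converged parameters —
  regression calibration, which keeps downstream log-linear effect
  estimates approximately unbiased under MCAR. Initialisation is
  deterministic: available-case means/variances, pairwise-complete
  correlations projected to the nearest positive-definite matrix
  (eigenvalue clipping at 1e-6). Negative imputed concentrations are
  floored at 0 and counted in the result. A `deseasonalize = TRUE` mode
  first removes per-pollutant harmonic (annual + semi-annual) means fitted
  to the observed values and imputes the residuals; the stationary joint
  model is the default because parameter recovery is already unbiased
  within the validated bands without it, but the seasonal mode is the
  safer choice when cycles are extreme.
* **Complete-case** (`complete_case()`): only days with all six pollutants
  observed. At realistic rates this keeps roughly
  $\prod_j (1 - r_j) \approx 12\%$ of days, and days whose *lagged*
  exposures are also fully observed become so sparse that distributed-lag
  fits are generally infeasible — the comparison report
  (`compare_imputation()`) therefore uses lag-0 models, and the precision
  loss it shows is the point of the sensitivity analysis.

Meteorology gaps of at most 2 days are linearly interpolated
(`interpolate_weather()`); longer gaps are an input error rather than a
guess. Station-level records are combined by `average_stations()`: the
city-day value is the mean of the non-missing stations, missing only when
all stations are missing.

## The synthetic-data generator

Because admission registries and monitor archives are rarely
redistributable, every estimator in the package is validated on synthetic
panels with known truth (`simulate_panel()`). The generator emulates a
six-year (2191-day) study in an industrial mid-latitude city:

* **Pollutants**: seasonal cosine mean (amplitude and peak day per
  pollutant; winter peaks for combustion products, a summer peak for O₃)
  plus cross-correlated Gaussian day-to-day noise (default: exchangeable
  0.4, O₃ at −0.15), truncated at a 0.1-unit positive floor. The
  truncation, rather than a log-normal, keeps the configured correlation
  matrix directly interpretable; it slightly distorts the far lower tail
  of PM₂.₅. Locations and scales default to the descriptive statistics of
  the motivating setting (e.g. NO₂ 53.45 µg/m³, CO 2.89 mg/m³).
* **Amplitude/phase convention**: amplitudes are constrained non-negative
  (a negative amplitude is a configuration error); the phase is carried by
  a per-variable peak day-of-year. Summer-peaking variables are encoded by
  their peak day, not by a sign.
* **Weather**: seasonal cycles plus noise; humidity clamped to 0–100%.
* **Counts**: negative-binomial with variance $\mu\varphi$ (Poisson when
  $\varphi = 1$); the default $\varphi = 1.5$ is a moderate overdispersion
  typical of daily admission series (the magnitude is a free parameter of
  the generator, not an empirical fact). The log-mean applies the true lag
  effects (default: RR 1.03 per 10 µg/m³ of NO₂ at lag 0, zero at lags
  1–7), weather coefficients and a seasonal term to covariates *centred at
  their configured means*, so `baseline_log_rate` is the log marginal mean
  count (default $\log 7.13$) — a pure reparameterization that leaves all
  slopes unchanged. Totals are split into sex (57.4% male) and age (31%
  aged 60+) strata by binomial thinning, so strata sum to the total on
  every day.
* **Burn-in**: seven lead days are generated before the first analysis day
  so every analysed day has lag-0..7 exposures; lead rows are flagged
  `burn_in` and carry no counts.
* **Degradation**: MCAR masking at per-pollutant rates (defaults 20% CO,
  25% PM₁₀, 30% PM₂.₅, 32% NO₂, 34% O₃, 35% SO₂), with an optional MAR
  mode (seasonally varying missingness at the same marginal rate) for
  robustness checks. **Stations**: city values are expanded into
  `n_stations = 4` station-day values with independent noise (sd 20% of
  the pollutant sd) and the same positivity floor.

What the generator does *not* emulate: autocorrelated pollutant noise
beyond the seasonal cycle, heavy-tailed episodes (dust storms,
inversions), measurement error correlated across stations, hourly
structure (O₃'s 8-h maximum is represented only as a daily scalar),
holiday surges in admissions, and reporting artefacts. Passing the
validation suite therefore demonstrates correctness of the estimators
under the stated data-generating mechanism, not robustness to every
failure mode of real registry data.

## Validation design and problem sizes

The test-suite validation uses these study conditions, chosen once as
realistic for the emulated design:

* **Parameter recovery**: 100 seeded replicates of the full pipeline
  (generate 2191 days → degrade → EM-impute → lag-0 fit) with true RR 1.03
  per 10 µg/m³; the suite requires the mean estimated RR within 0.005 of
  truth and 95% CI coverage within 0.90–0.98 (slight under-coverage is
  expected because single-imputation SEs ignore imputation uncertainty).
* **Confounder control**: 200 replicates of 1096-day (3-year) panels with
  zero true effects and strong shared seasonality (NO₂ annual amplitude 18
  µg/m³, outcome log-rate amplitude 0.4). The lag-0 test must reject at
  the nominal 5% level (binomial 99% bounds) with the 7 df/year time
  spline in the model, and at a substantially inflated rate without it —
  the time spline, not the weather or DOW blocks, is what breaks the
  season-to-season confounding.
* **Imputation quality**: on 20 seeded panels at the default missingness
  rates, EM imputation must beat per-pollutant mean imputation in relative
  RMSE on the masked cells, and the bivariate conditional-mean closed form
  must hold at the converged moments to 1e-6.
* **Exact identities**: IRLS vs brute-force ML (1e-6) on small fixtures,
  score equations $X^\top(y - \hat\mu) = 0$, saturated-strata equivalence
  (1e-8), natural-spline dimension/tail/span properties, Wald duality and
  the increment-scaling identity $\mathrm{RR}(\Delta) = \mathrm{RR}(1)^\Delta$.

These sizes keep a full run of the suite around half a minute while
leaving each stochastic check comfortably powered.

## Numerical choices and degenerate inputs

* IRLS: relative-deviance tolerance 1e-9, max 100 iterations,
  deterministic start, step-halving guard; rank deficiency errors with the
  offending column names.
* EM: log-likelihood tolerance 1e-6, max 500 iterations; non-convergence
  returns `converged = FALSE` with a warning rather than an error; a
  covariance that loses positive definiteness is an error with the
  missingness pattern named. Pre-conditions: every pollutant observed on
  at least 2 days and at least 7 partially observed rows.
* `select_df()` ties break toward the smaller (smoother) df; failed
  candidates are skipped with a warning, and only an all-fail set is an
  error.
* Constant exposure series make single-lag designs collinear with the
  intercept; this is reported as a rank-deficiency error naming the
  exposure column, per lag.
* Pipeline reproducibility: one RNG substream per stage (fixed offsets
  from the master seed), so toggling, say, the imputation mode never
  changes the simulated panel; manifests record md5 checksums of every
  output.

## Known limitations

* Single imputation: between-imputation variance is not propagated
  (multiple imputation is out of scope), hence the tolerated mild
  under-coverage.
* The EM model treats days as exchangeable; temporal autocorrelation in
  pollutant residuals is ignored (a Kalman-type imputer would exploit it).
* No autocorrelation-robust standard errors for the regression stage; the
  time spline is relied upon to remove serial structure in the mean.
* No multiple-testing correction across lags, pollutants or strata — the
  reporting convention mirrors standard practice in this literature and
  the p-values should be read accordingly.
* Exposure enters linearly; non-linear exposure–response surfaces and
  temperature lag structures are not modelled.
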