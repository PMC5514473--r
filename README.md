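# airlag

Distributed-lag quasi-Poisson time-series models linking daily ambient
air-pollutant concentrations (CO, SO₂, NO₂, O₃, PM₂.₅, PM₁₀) to daily
counts of respiratory hospital admissions.

`airlag` is aimed at environmental epidemiologists running the classical
ecological time-series design: aggregate daily exposure, aggregate daily
counts, confounding controlled through smooth functions of time and
weather. It covers the full workflow — multi-station averaging,
EM-algorithm imputation of missing pollutant series, design-matrix
assembly, quasi-Poisson fitting, and rate-ratio reporting — plus a
synthetic-data generator with known ground truth so every stage can be
validated without access to registry data.

## The model

Daily admission counts $Y_t$ follow an overdispersed count law with

$$
\log \mu_t = \alpha + \sum_{\ell=0}^{7} \beta_\ell\,\mathrm{AP}_{t-\ell}
  + s(\mathrm{time};\,7\,\mathrm{df/yr}) + s(T;\,4\,\mathrm{df})
  + s(H;\,4\,\mathrm{df}) + \gamma\,\mathrm{DOW},
$$

fitted by the package's own IRLS with a Pearson-dispersion quasi-Poisson
covariance. The exposure block comes in three variants — single-lag
(one model per lag), unconstrained distributed-lag (all 8 lags free), and
lag-stratified constrained distributed-lag (shared coefficients within
strata `{0}, {1,2}, {3..7}`) — and effects are reported as rate ratios per
10 µg/m³ (1 mg/m³ for CO) with 95% Wald intervals. Missing pollutant
values are imputed by EM under a joint multivariate normal model
(conditional-mean imputation at the converged parameters), with
complete-case analysis available as the sensitivity counterpart.
See `vignettes/airlag-methods.Rmd` for the full methods account.

## Worked example

Simulate a six-year study (2191 days, true rate ratio 1.03 per 10 µg/m³ of
NO₂ at lag 0), mask pollutants at realistic missingness rates (20–35% per
pollutant), impute by EM, and fit the distributed-lag model:

```r
library(airlag)

cfg <- sim_config(seed = 42)                 # study-sized defaults
gen <- simulate_panel(cfg)                   # panel + ground truth
deg <- degrade_missing(gen$panel, cfg, seed = 43)
em  <- em_impute(deg)
em
#> EM imputation of 6 pollutants: 16 iterations, converged (final log-likelihood -36350.721)
#> 2 imputed values floored at 0

eff <- run_dlm_suite(em$panel, "no2", mode = "unconstrained")
format_effects(eff)
#>   pollutant stratum         model lag                 rr_ci       p
#> 1       no2     all unconstrained   0    1.031 (1.02-1.043) 1.0e-07
#> 2       no2     all unconstrained   1 0.9915 (0.9804-1.003) 1.4e-01
#> 3       no2     all unconstrained   2  1.001 (0.9901-1.013) 8.2e-01
#> 4       no2     all unconstrained   3  1.007 (0.9956-1.018) 2.3e-01
#> 5       no2     all unconstrained   4  1.005 (0.9932-1.016) 4.3e-01
#> 6       no2     all unconstrained   5 0.9995 (0.9883-1.011) 9.3e-01
#> 7       no2     all unconstrained   6 0.9995 (0.9882-1.011) 9.3e-01
#> 8       no2     all unconstrained   7  1.007 (0.9952-1.018) 2.6e-01
```

The lag-0 rate ratio is estimated at 1.031 (95% CI 1.02–1.043) against a
generator truth of 1.03 per 10 µg/m³, while the seven null lags straddle 1
— the confounder blocks have absorbed the shared seasonality. Subgroup
(`run_subgroups()`), two-pollutant (`run_two_pollutant()`) and
single-lag (`run_single_lag_suite()`) suites follow the same pattern, and
`plot_effects(eff)` draws the lag–RR forest plot.

End-to-end seeded runs with manifests and CSV outputs:

```r
man <- run_pipeline(run_config(input_mode = "simulate", pollutants = "no2",
                               out_dir = "run1", seed = 7))
```

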