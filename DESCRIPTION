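Package: airlag
Title: Distributed-Lag Quasi-Poisson Time-Series Models for Air Pollution
    and Daily Hospital Admissions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ecological time-series studies linking daily ambient
    air-pollutant concentrations to daily counts of hospital admissions.
    Provides a synthetic daily-panel generator with known ground-truth lag
    effects, seasonal confounding and overdispersion; station averaging and
    EM-algorithm imputation of missing pollutant series under a multivariate
    normal model; natural cubic spline confounder bases for long-term trend,
    temperature and relative humidity; quasi-Poisson distributed-lag
    regression fitted by iteratively reweighted least squares with
    quasi-AIC model selection; and rate-ratio estimation per reporting
    increment across lags, sex and age subgroups, and two-pollutant models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    jsonlite,
    yaml,
    zoo,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
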