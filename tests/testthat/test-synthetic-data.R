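# Synthetic daily-panel generator

test_that("seeded panels are exactly reproducible", {
  cfg <- small_config(seed = 11)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$mu, b$truth$mu)
})

test_that("null configuration reproduces the configured baseline mean", {
  cfg <- null_config(seed = 3)
  gen <- simulate_panel(cfg)
  y <- gen$panel$all[!gen$panel$burn_in]
  expect_length(y, 2191)
  se <- sqrt(7.13 / length(y))
  expect_lt(abs(mean(y) - 7.13), 3 * se)
  # the stored true mean is the exponentiated linear predictor on every day
  expect_equal(gen$truth$mu[!gen$panel$burn_in], rep(7.13, 2191))
})

test_that("equidispersed counts have variance/mean ratio near 1", {
  cfg <- null_config(n_days = 10000L, seed = 5, overdispersion = 1)
  y <- simulate_panel(cfg)$panel$all
  y <- y[!is.na(y)]
  ratio <- var(y) / mean(y)
  expect_lt(abs(ratio - 1), 3 * sqrt(2 / length(y)) + 0.01)
})

test_that("overdispersed counts match the configured variance/mean ratio", {
  cfg <- null_config(n_days = 10000L, seed = 6, overdispersion = 2)
  y <- simulate_panel(cfg)$panel$all
  y <- y[!is.na(y)]
  expect_gt(var(y) / mean(y), 1.7)
  expect_lt(var(y) / mean(y), 2.3)
})

test_that("null counts match the configured Poisson law (PIT + KS)", {
  cfg <- null_config(n_days = 10000L, seed = 8)
  y <- simulate_panel(cfg)$panel$all
  y <- y[!is.na(y)]
  set.seed(99)
  u <- ppois(y - 1, 7.13) + runif(length(y)) * dpois(y, 7.13)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("sex and age strata sum to the daily total", {
  gen <- simulate_panel(small_config(seed = 2))
  p <- gen$panel[!gen$panel$burn_in, ]
  expect_true(all(p$male + p$female == p$all))
  expect_true(all(p$under60 + p$over60 == p$all))
})

test_that("harmonic regression recovers the configured seasonal amplitude", {
  cfg <- sim_config(n_days = 2191L, seed = 13)
  gen <- simulate_panel(cfg)
  doy <- as.POSIXlt(gen$panel$date)$yday + 1
  for (v in c("no2", "o3")) {
    ph <- 2 * pi * (doy - cfg$seasonal_peaks[[v]]) / 365.25
    fit <- lm(gen$panel[[v]] ~ cos(ph) + sin(ph))
    est <- coef(summary(fit))["cos(ph)", ]
    expect_lt(abs(est["Estimate"] - cfg$seasonal_amplitudes[[v]]),
              3 * est["Std. Error"])
  }
})

test_that("configuration invariants are enforced", {
  badR <- matrix(0.99, 6, 6); diag(badR) <- 1
  badR[1, 2] <- badR[2, 1] <- -0.99
  expect_error(sim_config(pollutant_correlation = badR), "positive definite")
  expect_error(sim_config(seasonal_amplitudes = c(no2 = -1)), "non-negative")
  expect_error(sim_config(missing_rates = c(co = 1)), "\\[0, 1\\)")
  expect_error(sim_config(lag_log_rr = rep(0, 7)), "8 entries")
  expect_error(sim_config(strata_shares = list(sex = c(male = 0.6, female = 0.6),
                                               age = c(under60 = 0.7, over60 = 0.3))),
               "sum to 1")
  expect_error(sim_config(overdispersion = 0.5), "overdispersion")
})

test_that("degradation masks at the configured rates and nothing else", {
  cfg <- sim_config(n_days = 2191L, seed = 21)
  gen <- simulate_panel(cfg)

  # zero rates: identity
  same <- degrade_missing(gen$panel, setNames(rep(0, 6), POLL), seed = 1)
  expect_identical(same[POLL], gen$panel[POLL])

  deg <- degrade_missing(gen$panel, cfg, seed = 22)
  mask <- attr(deg, "miss_mask")
  n <- nrow(deg)
  for (v in c("co", "so2")) {
    r <- cfg$missing_rates[[v]]
    bounds <- stats::qbinom(c(0.005, 0.995), n, r) / n
    expect_gte(mean(is.na(deg[[v]])), bounds[1])
    expect_lte(mean(is.na(deg[[v]])), bounds[2])
  }
  # unmasked entries are bitwise identical
  for (v in POLL) {
    expect_identical(deg[[v]][!mask[, v]], gen$panel[[v]][!mask[, v]])
  }
  expect_error(degrade_missing(gen$panel, c(co = 1.2)), "\\[0, 1\\)")
  expect_error(degrade_missing(deg, cfg), "complete")
})

test_that("MAR degradation keeps the marginal rate but varies seasonally", {
  cfg <- sim_config(n_days = 2191L, seed = 31)
  gen <- simulate_panel(cfg)
  deg <- degrade_missing(gen$panel, cfg, mechanism = "mar", seed = 32)
  r <- mean(is.na(deg$no2))
  expect_lt(abs(r - 0.32), 0.04)
  month <- as.POSIXlt(deg$date)$mon
  winter <- mean(is.na(deg$no2[month %in% c(11, 0, 1)]))
  summer <- mean(is.na(deg$no2[month %in% c(5, 6, 7)]))
  expect_gt(winter, summer)
})

test_that("station expansion is unbiased and has the configured noise", {
  cfg <- small_config(seed = 41, station_sds = setNames(rep(0, 6), POLL))
  gen <- simulate_panel(cfg)

  one <- split_stations(gen$panel, sim_config(n_days = 730L, n_stations = 1,
                                              station_sds = setNames(rep(0, 6), POLL)))
  expect_equal(one$no2, gen$panel$no2)

  four0 <- split_stations(gen$panel, cfg, seed = 1)
  avg <- average_stations(four0)
  expect_equal(avg$no2, gen$panel$no2)

  cfg_sd <- small_config(seed = 41, station_sds = setNames(rep(3, 6), POLL))
  four <- split_stations(gen$panel, cfg_sd, seed = 2)
  # pooled station noise sd approximates the configured sigma over many days
  resid <- four$no2 - rep(gen$panel$no2, each = 4)
  expect_lt(abs(sd(resid) - 3), 0.1)
  # and the per-day station mean is centred on the city value
  avg_sd <- average_stations(four)
  expect_lt(abs(mean(avg_sd$no2 - gen$panel$no2)), 0.15)
})

test_that("panels round-trip through CSV with ISO dates and empty NAs", {
  cfg <- small_config(seed = 51)
  gen <- simulate_panel(cfg)
  deg <- degrade_missing(gen$panel, cfg, seed = 52)
  f <- tempfile(fileext = ".csv")
  write_panel(deg, f)
  back <- read_panel(f)
  expect_equal(back$date, deg$date)
  expect_equal(back$no2, deg$no2)
  expect_equal(back$all, deg$all)
  line1 <- readLines(f, n = 2)
  expect_match(line1[2], "^2009-12-25,")  # ISO-8601, 7 lead days before start
})

test_that("truth sidecar round-trips", {
  gen <- simulate_panel(small_config(seed = 61))
  f <- tempfile(fileext = ".json")
  write_truth(gen$truth, f)
  back <- read_truth(f)
  expect_equal(back$lag_log_rr, gen$truth$lag_log_rr)
  expect_equal(back$mu, gen$truth$mu)
})
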