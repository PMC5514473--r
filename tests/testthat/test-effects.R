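# Rate-ratio reporting and the model suites

test_that("rr_from_coef matches direct exponentiation and Wald arithmetic", {
  z0 <- rr_from_coef(0, 0.02, 10)
  expect_equal(z0$rr, 1)
  expect_equal(z0$p_value, 1)
  expect_equal(z0$ci_low * z0$ci_high, 1, tolerance = 1e-12)  # centred at 1

  e <- rr_from_coef(0.0031511, 0.0014, 10)
  expect_equal(e$rr, exp(0.031511), tolerance = 1e-10)
  expect_equal(e$rr, 1.0320, tolerance = 1e-4)
  expect_equal(e$ci_low, 1.0041, tolerance = 1e-4)
  expect_equal(e$ci_high, 1.0607, tolerance = 1e-4)

  # increment scaling identity: RR(10) = RR(1)^10
  r1 <- rr_from_coef(0.0031511, 0.0014, 1)
  expect_equal(e$rr, r1$rr^10, tolerance = 1e-12)
  expect_equal(e$ci_low, r1$ci_low^10, tolerance = 1e-12)
})

test_that("CO effects are reported per 1 mg/m3, others per 10 ug/m3", {
  expect_equal(reporting_increment("co"), 1)
  expect_equal(reporting_increment("no2"), 10)
  gen <- simulate_panel(small_config(seed = 301))
  eff <- run_single_lag_suite(gen$panel, "co", lags = 0)
  expect_equal(eff$increment, 1)
  expect_equal(eff$rr, exp(eff$beta), tolerance = 1e-12)
})

test_that("single-lag suite recovers a pure lag-0 effect and leaves other lags null", {
  cfg <- sim_config(n_days = 1096L, seed = 311,
                    lag_log_rr = c(log(1.05) / 10, rep(0, 7)))
  gen <- simulate_panel(cfg)
  eff <- run_single_lag_suite(gen$panel, "no2")
  expect_equal(nrow(eff), 8)
  lag0 <- eff[eff$lag == 0, ]
  expect_lt(abs(lag0$beta - log(1.05) / 10), 3 * lag0$se)
  others <- eff[eff$lag != 0, ]
  expect_gte(sum(others$ci_low <= 1 & 1 <= others$ci_high), 6)
})

test_that("constrained DLM repeats the stratum estimate at member lags", {
  gen <- simulate_panel(small_config(seed = 321))
  eff <- run_dlm_suite(gen$panel, "no2", mode = "constrained")
  expect_equal(nrow(eff), 8)
  expect_equal(eff$rr[eff$lag == 1], eff$rr[eff$lag == 2])
  expect_equal(length(unique(eff$rr[eff$lag >= 3])), 1L)
  expect_equal(unique(eff$lag_stratum), c("0", "1-2", "3-7"))
})

test_that("saturated-strata constrained DLM reproduces the unconstrained fit", {
  gen <- simulate_panel(small_config(seed = 331))
  un <- run_dlm_suite(gen$panel, "no2", mode = "unconstrained")
  sat <- run_dlm_suite(gen$panel, "no2", mode = "constrained",
                       strata = as.list(0:7))
  expect_equal(sat$rr, un$rr, tolerance = 1e-8)
  expect_equal(sat$se, un$se, tolerance = 1e-8)
})

test_that("constrained DLM is more efficient when effects are shared within strata", {
  # truth: equal effects within {1,2}; compare Monte-Carlo SD at lag 1
  est <- t(sapply(1:25, function(i) {
    cfg <- sim_config(n_days = 730L, seed = 500 + i,
                      lag_log_rr = c(0, rep(log(1.04) / 10, 2), rep(0, 5)))
    gen <- simulate_panel(cfg)
    c(un = run_dlm_suite(gen$panel, "no2", mode = "unconstrained")$beta[2],
      con = run_dlm_suite(gen$panel, "no2", mode = "constrained")$beta[2])
  }))
  expect_lt(sd(est[, "con"]), sd(est[, "un"]))
})

test_that("subgroup runs label strata and agree under common effects", {
  cfg <- sim_config(n_days = 1096L, seed = 341,
                    lag_log_rr = c(log(1.05) / 10, rep(0, 7)),
                    strata_shares = list(sex = c(male = 0.5, female = 0.5),
                                         age = c(under60 = 0.69, over60 = 0.31)))
  gen <- simulate_panel(cfg)
  eff <- run_subgroups(gen$panel, "no2", strata = c("male", "female"),
                       suite = "single", lags = 0)
  expect_setequal(eff$stratum, c("male", "female"))
  bm <- eff[eff$stratum == "male", ]
  bf <- eff[eff$stratum == "female", ]
  expect_lt(abs(bm$beta - bf$beta), 3 * sqrt(bm$se^2 + bf$se^2))

  # stratum 'all' reproduces the unstratified run
  all1 <- run_subgroups(gen$panel, "no2", strata = "all", suite = "single",
                        lags = 0)
  all2 <- run_single_lag_suite(gen$panel, "no2", lags = 0)
  expect_equal(all1$rr, all2$rr)

  zero <- gen$panel
  zero$male[] <- 0L
  zero$female <- zero$all
  expect_error(run_subgroups(zero, "no2", strata = "male", suite = "single"),
               "all-zero")
})

test_that("two-pollutant adjustment leaves an unconfounded effect unchanged", {
  cfg <- sim_config(n_days = 1096L, seed = 351,
                    lag_log_rr = c(log(1.05) / 10, rep(0, 7)),
                    pollutant_correlation = diag(6) |>
                      (\(m) {dimnames(m) <- list(POLL, POLL); m})())
  gen <- simulate_panel(cfg)
  unadj <- run_single_lag_suite(gen$panel, "no2", lags = 0)
  adj <- run_two_pollutant(gen$panel, "no2", "so2")
  expect_lt(abs(adj$beta - unadj$beta), unadj$se)
  expect_equal(adj$co_pollutant, "so2")
  expect_error(run_two_pollutant(gen$panel, "no2", "no2"), "differ")
})

test_that("Wald duality and increment coherence hold for every emitted estimate", {
  gen <- simulate_panel(small_config(seed = 361))
  eff <- rbind(
    run_single_lag_suite(gen$panel, "no2"),
    run_dlm_suite(gen$panel, "no2", mode = "unconstrained"),
    run_dlm_suite(gen$panel, "no2", mode = "constrained"),
    run_two_pollutant(gen$panel, "no2", "pm10")
  )
  excludes_1 <- eff$ci_low > 1 | eff$ci_high < 1
  expect_identical(excludes_1, eff$p_value < 0.05)
  expect_true(all(eff$ci_low <= eff$rr & eff$rr <= eff$ci_high))
  expect_equal(eff$rr, exp(eff$beta)^eff$increment, tolerance = 1e-12)
})

test_that("formatted output and forest plot render", {
  gen <- simulate_panel(small_config(seed = 371))
  eff <- run_dlm_suite(gen$panel, "no2", mode = "unconstrained")
  fmt <- format_effects(eff)
  expect_match(fmt$rr_ci[1], "^[0-9.]+ \\([0-9.]+-[0-9.]+\\)$")
  p <- plot_effects(eff)
  expect_s3_class(p, "ggplot")
})
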