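# Natural cubic spline bases, lag bases, day-of-week terms, assembly

test_that("natural cubic basis has df columns and is linear beyond the boundary", {
  x <- seq(0, 10, length.out = 200)
  for (df in c(1, 4, 7)) {
    B <- natural_cubic_basis(x, df)
    expect_equal(ncol(B), df)
  }
  # df = 1: the single column is an affine function of x
  B1 <- natural_cubic_basis(x, 1)
  res <- lm.fit(cbind(1, x), B1[, 1])$residuals
  expect_lt(max(abs(res)), 1e-10)
  # numerically evaluated second derivative vanishes beyond the boundary knots
  B <- natural_cubic_basis(x, 4)
  h <- 0.05
  for (x0 in c(-2, -1, 11, 12.5)) {
    pts <- predict_basis(B, c(x0 - h, x0, x0 + h))
    d2 <- (pts[1, ] - 2 * pts[2, ] + pts[3, ]) / h^2
    expect_lt(max(abs(d2)), 1e-6)
  }
  expect_error(natural_cubic_basis(rep(1:3, 10), 4), "too few distinct")
})

test_that("basis spans a hand-built truncated-power natural cubic spline", {
  x <- 1:100
  B <- natural_cubic_basis(x, 4)
  knots <- c(attr(B, "Boundary.knots")[1], attr(B, "knots"),
             attr(B, "Boundary.knots")[2])
  K <- length(knots)
  # truncated-power natural spline basis (ESL 5.2.1): 1, x, N_1..N_{K-2}
  dk <- function(k, x) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  Nfun <- sapply(seq_len(K - 2), function(j) dk(j, x) - dk(K - 1, x))
  g <- 2 - 0.5 * x + Nfun %*% c(0.3, -0.2, 0.1, 0.05)[seq_len(K - 2)]
  fit <- lm.fit(cbind(1, B), g)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("time spline df follows round(df_per_year * span / 365.25)", {
  d0 <- as.Date("2010-01-01")
  expect_equal(ncol(time_spline(seq(d0, by = "day", length.out = 2191), 7)), 42)
  expect_equal(ncol(time_spline(seq(d0, by = "day", length.out = 365), 1)), 1)
  expect_equal(ncol(time_spline(seq(d0, by = "day", length.out = 730), 7)), 14)
  expect_error(time_spline(seq(d0, by = "day", length.out = 100), 1),
               "too short")
})

test_that("lag bases implement the three model variants", {
  x <- c(1, 2, 3, 4, 5)
  un <- lag_basis(x, lag_structure("unconstrained", max_lag = 2))
  expect_equal(unname(un[3, ]), c(3, 2, 1))
  expect_equal(ncol(un), 3)
  expect_equal(which(attr(un, "complete_row")), 3:5)

  expect_equal(ncol(lag_basis(rep(1, 10), lag_structure("unconstrained"))), 8)
  con <- lag_basis(rep(2, 20), lag_structure("constrained"))
  expect_equal(ncol(con), 3)
  ok <- attr(con, "complete_row")
  expect_true(all(con[ok, 1] == 2 & con[ok, 2] == 4 & con[ok, 3] == 10))

  single <- lag_basis(x, lag_structure("single", max_lag = 2, lag = 2))
  expect_equal(unname(single[3:5, 1]), c(1, 2, 3))

  expect_error(lag_basis(c(1, NA, 3), lag_structure("single", lag = 0)),
               "missing")
  expect_error(lag_structure("constrained", strata = list(0:1, 1:7)),
               "partition")
  expect_error(lag_structure("single"), "requires a lag")
})

test_that("calendar-aware lagging respects date gaps", {
  dates <- as.Date("2020-01-01") + c(0:4, 7:9)  # days 6-7 absent
  x <- as.numeric(seq_along(dates))
  B <- lag_basis(x, lag_structure("single", max_lag = 1, lag = 1), dates = dates)
  expect_true(is.na(B[6, 1]))        # 2020-01-08 has no 2020-01-07 value
  expect_equal(unname(B[7, 1]), 6)   # 2020-01-09's lag-1 is 2020-01-08
})

test_that("day-of-week terms use Saturday as reference; holiday mode counts days", {
  dates <- seq(as.Date("2020-01-04"), by = "day", length.out = 7)  # Sat..Fri
  M <- dow_terms(dates)
  expect_equal(ncol(M), 6)
  expect_equal(unname(colSums(M)), rep(1, 6))
  expect_equal(unname(M[1, ]), rep(0, 6))  # Saturday row is all zero

  d5 <- seq(as.Date("2020-01-01"), by = "day", length.out = 5)
  h <- dow_terms(d5, "days_since_holiday", holidays = d5[1])
  expect_equal(unname(h[, 1]), c(0, 1, 2, 3, 4))
  hall <- dow_terms(d5, "days_since_holiday", holidays = d5)
  expect_equal(unname(hall[, 1]), rep(0, 5))
  expect_error(dow_terms(d5, "days_since_holiday"), "holiday calendar")
})

test_that("assembled designs have the documented block arithmetic", {
  gen <- simulate_panel(sim_config(n_days = 2191L, seed = 171))
  d_un <- assemble_design(gen$panel, "no2", lag_structure("unconstrained"))
  expect_equal(ncol(d_un$X), 1 + 8 + 42 + 4 + 4 + 6)  # 65
  expect_equal(nrow(d_un$X), 2191)
  d_si <- assemble_design(gen$panel, "no2",
                          lag_structure("single", max_lag = 7, lag = 0))
  expect_equal(ncol(d_si$X), 58)
  d_two <- assemble_design(gen$panel, "no2",
                           lag_structure("single", max_lag = 7, lag = 0),
                           second_pollutant = "co")
  expect_equal(ncol(d_two$X), 59)
  # exposure columns map back to lags exactly once
  expect_equal(sort(unlist(d_un$lag_map)), 0:7)
  expect_equal(length(d_un$blocks$exposure), length(d_un$lag_map))
  # full column rank on generic data
  expect_equal(qr(d_un$X)$rank, ncol(d_un$X))
})

test_that("assembly errors name the offending cell and config problems", {
  gen <- simulate_panel(small_config(seed = 181))
  p <- gen$panel
  p$no2[33] <- NA
  expect_error(assemble_design(p, "no2", lag_structure("unconstrained")),
               "no2.*row 33")
  expect_error(assemble_design(gen$panel, "no2",
                               lag_structure("single", max_lag = 0, lag = 0),
                               second_pollutant = "no2"),
               "differ")
})

test_that("fitted values are invariant under a constant date shift", {
  gen <- simulate_panel(small_config(seed = 191))
  d1 <- assemble_design(gen$panel, "no2", lag_structure("unconstrained"))
  shifted <- gen$panel
  shifted$date <- shifted$date + 1000
  d2 <- assemble_design(shifted, "no2", lag_structure("unconstrained"))
  f1 <- qp_fit(d1)
  f2 <- qp_fit(d2)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
})

test_that("design export writes matrix plus column metadata sidecar", {
  gen <- simulate_panel(small_config(seed = 195))
  d <- assemble_design(gen$panel, "co", lag_structure("constrained"))
  f <- tempfile(fileext = ".csv")
  write_design(d, f)
  expect_true(file.exists(f))
  meta <- jsonlite::read_json(paste0(f, ".meta.json"), simplifyVector = TRUE)
  expect_equal(meta$pollutant, "co")
  expect_equal(length(meta$blocks$exposure), 3)
})
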