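# Shared fixtures: small, fast synthetic configurations and a brute-force
# Poisson maximum-likelihood oracle independent of the IRLS code path.

POLL <- c("co", "so2", "no2", "o3", "pm25", "pm10")

# A small panel configuration for module tests (2 years).
small_config <- function(seed = 1, ...) {
  sim_config(n_days = 730L, seed = seed, ...)
}

# A null configuration: constant mean, no covariate effects, Poisson counts.
null_config <- function(n_days = 2191L, seed = 1, overdispersion = 1,
                        baseline_log_rate = log(7.13)) {
  amps <- setNames(rep(0, 9), c(POLL, "temp", "humidity", "rate"))
  sim_config(n_days = n_days, seed = seed,
             baseline_log_rate = baseline_log_rate,
             lag_log_rr = rep(0, 8),
             seasonal_amplitudes = amps,
             weather_effect = c(temp = 0, humidity = 0),
             overdispersion = overdispersion)
}

# Brute-force Poisson ML via a generic optimizer (BFGS on the analytic
# log-likelihood); independent of the IRLS implementation.
brute_force_poisson <- function(y, X, start = NULL) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - exp(eta))
  }
  grad <- function(b) {
    mu <- exp(drop(X %*% b))
    -drop(crossprod(X, y - mu))
  }
  if (is.null(start)) start <- rep(0, ncol(X))
  opt <- optim(start, nll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# Deterministic small count-regression fixture.
glm_fixture <- function(n = 30, p = 3, seed = 7) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  beta <- c(1.2, 0.3, -0.2, 0.15)[seq_len(p)]
  y <- rpois(n, exp(drop(X %*% beta)))
  list(y = y, X = X, beta = beta)
}
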