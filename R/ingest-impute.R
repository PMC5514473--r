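# Station averaging, EM imputation of the pollutant vector, and the
# complete-case alternative.
#
# The imputation model is a 6-dimensional multivariate normal over the daily
# pollutant vector, days independent. The EM algorithm maximizes the
# observed-data likelihood over the missingness patterns; missing entries are
# replaced by their conditional means given the observed entries at the
# converged parameters (regression calibration). An optional mode removes
# per-pollutant harmonic seasonal means first and imputes the residuals,
# which respects the strong annual cycles of pollutant series.

#' Average station measurements into city-day values
#'
#' The city-day value of each pollutant is the arithmetic mean of the
#' non-missing station values for that day; when a station is missing the
#' average of the remaining stations is used, and the city value is missing
#' only when every station is missing.
#'
#' @param stations a station panel: columns `date`, `station` and the six
#'   pollutants, one row per (date, station).
#' @return a data.frame with one row per date and the six averaged pollutant
#'   columns.
#' @export
average_stations <- function(stations) {
  if (nrow(stations) == 0) stop("empty station panel")
  if (anyDuplicated(stations[c("date", "station")])) {
    stop("duplicate (date, station) rows in station panel")
  }
  neg <- vapply(POLLUTANTS, function(p) any(stations[[p]] < 0, na.rm = TRUE),
                logical(1))
  if (any(neg)) {
    warning("negative station values in: ", paste(POLLUTANTS[neg], collapse = ", "))
  }
  mean_obs <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- aggregate(stations[POLLUTANTS], by = list(date = stations$date), mean_obs)
  out[order(out$date), , drop = FALSE]
}

# Project a correlation matrix to the nearest positive-definite one by
# eigenvalue clipping, then rescale to unit diagonal.
nearest_pd_corr <- function(R, eps = 1e-6) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  S <- e$vectors %*% (vals * t(e$vectors))
  D <- 1 / sqrt(diag(S))
  S <- S * tcrossprod(D)
  (S + t(S)) / 2
}

# Core EM for a multivariate normal with missing entries.
# X: numeric matrix with NAs. Returns mean, covariance, log-likelihood
# trace (evaluated at the parameters entering each E-step), iteration count
# and convergence flag, plus the imputed matrix (conditional means).
em_mvnorm <- function(X, tol = 1e-6, max_iter = 500L,
                      mu0 = NULL, sigma0 = NULL) {
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  n_obs_var <- colSums(obs)
  if (any(n_obs_var < 2)) {
    stop("variables with fewer than 2 observed values: ",
         paste(colnames(X)[n_obs_var < 2], collapse = ", "))
  }
  if (sum(rowSums(obs) > 0) < p + 1) {
    stop("too few partially observed rows to identify the covariance")
  }
  if (tol <= 0) stop("tol must be positive")

  if (is.null(mu0)) mu0 <- colMeans(X, na.rm = TRUE)
  if (is.null(sigma0)) {
    v <- apply(X, 2, var, na.rm = TRUE)
    v[!is.finite(v) | v <= 0] <- 1e-6
    R <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    R <- nearest_pd_corr(R)
    sigma0 <- diag(sqrt(v), p) %*% R %*% diag(sqrt(v), p)
  }
  mu <- mu0
  Sigma <- (sigma0 + t(sigma0)) / 2

  pat <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    ll <- 0
    for (g in groups) {
      o <- which(obs[g[1L], ])
      m <- setdiff(seq_len(p), o)
      k <- length(g)
      Xg <- X[g, , drop = FALSE]
      if (length(o) == 0L) {
        Xg[] <- rep(mu, each = k)
        S2[m, m] <- S2[m, m] + k * Sigma
      } else {
        ch <- tryCatch(chol(Sigma[o, o, drop = FALSE]), error = function(e) NULL)
        if (is.null(ch)) {
          stop("covariance update lost positive definiteness at iteration ",
               iter, " (pattern with observed set {",
               paste(colnames(X)[o], collapse = ","), "})")
        }
        D <- sweep(Xg[, o, drop = FALSE], 2, mu[o])        # k x |o|
        z <- backsolve(ch, t(D), transpose = TRUE)          # |o| x k
        ll <- ll - 0.5 * k * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch)))) -
          0.5 * sum(z * z)
        if (length(m)) {
          B <- Sigma[m, o, drop = FALSE] %*% chol2inv(ch)   # m x |o|
          Xg[, m] <- matrix(mu[m], k, length(m), byrow = TRUE) + D %*% t(B)
          Cmm <- Sigma[m, m, drop = FALSE] - B %*% Sigma[o, m, drop = FALSE]
          S2[m, m] <- S2[m, m] + k * Cmm
        }
      }
      S1 <- S1 + colSums(Xg)
      S2 <- S2 + crossprod(Xg)
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L && abs(ll - ll_trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    mu_new <- S1 / n
    Sigma_new <- S2 / n - tcrossprod(mu_new)
    mu <- mu_new
    Sigma <- (Sigma_new + t(Sigma_new)) / 2
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations (last change ",
            format(abs(diff(utils::tail(ll_trace, 2)))), ")")
  }

  # final E-step imputation at the parameters the last log-likelihood used
  Ximp <- X
  for (g in groups) {
    o <- which(obs[g[1L], ])
    m <- setdiff(seq_len(p), o)
    if (!length(m)) next
    k <- length(g)
    if (!length(o)) {
      Ximp[g, ] <- rep(mu, each = k)
    } else {
      ch <- chol(Sigma[o, o, drop = FALSE])
      B <- Sigma[m, o, drop = FALSE] %*% chol2inv(ch)
      D <- sweep(X[g, o, drop = FALSE], 2, mu[o])
      Ximp[g, m] <- matrix(mu[m], k, length(m), byrow = TRUE) + D %*% t(B)
    }
  }
  dimnames(Sigma) <- list(colnames(X), colnames(X))
  list(imputed = Ximp, mean = setNames(mu, colnames(X)), cov = Sigma,
       loglik = ll_trace, iterations = iter, converged = converged)
}

# Harmonic (annual + semi-annual) seasonal mean fitted to observed values.
harmonic_fit <- function(x, doy) {
  H <- cbind(cos(2 * pi * doy / 365.25), sin(2 * pi * doy / 365.25),
             cos(4 * pi * doy / 365.25), sin(4 * pi * doy / 365.25))
  keep <- !is.na(x)
  fit <- lm.fit(cbind(1, H[keep, , drop = FALSE]), x[keep])
  drop(cbind(1, H) %*% fit$coefficients)
}

#' EM imputation of missing pollutant values
#'
#' Fits a 6-dimensional multivariate normal to the daily pollutant vectors
#' by the EM algorithm over the missingness patterns and replaces missing
#' entries by their conditional means given the observed entries at the
#' converged parameters. The observed-data log-likelihood is non-decreasing
#' across iterations; convergence is declared when it changes by less than
#' `tol`. Negative imputed concentrations are floored at 0 (concentrations
#' are physical) and the number of floored cells is reported.
#'
#' @param panel a daily panel with missing pollutant entries.
#' @param tol convergence tolerance on the observed-data log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param deseasonalize if `TRUE`, per-pollutant harmonic seasonal means
#'   (annual + semi-annual, fitted to the observed values) are removed
#'   before the EM and added back afterwards, so the multivariate normal is
#'   fitted to the (approximately stationary) residuals.
#' @param mu0,sigma0 optional starting values for the mean and covariance
#'   (defaults: available-case means and variances, pairwise-complete
#'   correlations projected to the nearest positive-definite matrix).
#' @return an object of class `"em_result"`: the imputed `panel` (zero
#'   missing pollutant entries, observed cells untouched), the estimated
#'   `mean` and `cov` of the pollutant vector (on the deseasonalized scale
#'   when `deseasonalize = TRUE`), the `loglik` trace, `iterations`,
#'   `converged`, and `n_floored`.
#' @export
em_impute <- function(panel, tol = 1e-6, max_iter = 500L,
                      deseasonalize = FALSE, mu0 = NULL, sigma0 = NULL) {
  validate_panel(panel)
  X <- as.matrix(panel[POLLUTANTS])
  seas <- NULL
  if (deseasonalize) {
    doy <- as.POSIXlt(panel$date)$yday + 1
    seas <- vapply(POLLUTANTS, function(v) harmonic_fit(X[, v], doy),
                   numeric(nrow(X)))
    X <- X - seas
  }
  em <- em_mvnorm(X, tol = tol, max_iter = max_iter, mu0 = mu0, sigma0 = sigma0)
  imp <- em$imputed
  if (deseasonalize) imp <- imp + seas
  was_missing <- is.na(as.matrix(panel[POLLUTANTS]))
  floored <- imp < 0 & was_missing
  imp[floored] <- 0
  out <- panel
  out[POLLUTANTS] <- imp
  res <- list(panel = out, mean = em$mean, cov = em$cov,
              loglik = em$loglik, iterations = em$iterations,
              converged = em$converged, n_floored = sum(floored),
              deseasonalized = deseasonalize)
  class(res) <- "em_result"
  res
}

#' @export
print.em_result <- function(x, ...) {
  cat("EM imputation of", length(POLLUTANTS), "pollutants:",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(final log-likelihood %.3f)\n", utils::tail(x$loglik, 1)))
  if (x$n_floored > 0) cat(x$n_floored, "imputed values floored at 0\n")
  invisible(x)
}

#' Write the EM log-likelihood trace as a diagnostic CSV
#'
#' @param em an `em_result`.
#' @param path file path.
#' @export
write_em_trace <- function(em, path) {
  write.csv(data.frame(iteration = seq_along(em$loglik), loglik = em$loglik),
            path, row.names = FALSE)
  invisible(path)
}

#' Complete-case filtering
#'
#' Keeps only days on which all six pollutants are observed — the
#' sensitivity analysis counterpart to EM imputation. Downstream design
#' assembly tolerates the resulting calendar gaps: lags and the time spline
#' are evaluated on calendar time, not on the row index.
#'
#' @param panel a daily panel.
#' @return the panel restricted to complete days.
#' @export
complete_case <- function(panel) {
  keep <- complete.cases(panel[POLLUTANTS])
  if (!any(keep)) stop("no complete days in panel")
  panel[keep, , drop = FALSE]
}

#' Interpolate short gaps in the meteorology series
#'
#' Gaps of at most `max_gap` consecutive missing days in `temp` or
#' `humidity` are filled by linear interpolation; longer gaps are an input
#' error (the analysis model requires same-day weather on every day).
#'
#' @param panel a daily panel.
#' @param max_gap longest gap (days) that may be interpolated.
#' @return the panel with interpolated weather columns.
#' @export
interpolate_weather <- function(panel, max_gap = 2L) {
  for (v in c("temp", "humidity")) {
    x <- panel[[v]]
    if (!anyNA(x)) next
    r <- rle(is.na(x))
    if (any(r$lengths[r$values] > max_gap)) {
      stop("gap longer than ", max_gap, " days in '", v, "'")
    }
    panel[[v]] <- zoo::na.approx(x, x = as.numeric(panel$date), na.rm = FALSE)
    if (anyNA(panel[[v]])) stop("gap at the boundary of '", v, "' cannot be interpolated")
  }
  panel
}
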