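# Log-link count regression by iteratively reweighted least squares with a
# quasi-Poisson dispersion.
#
# The point estimates maximize the Poisson log-likelihood; overdispersion is
# accommodated by the Pearson dispersion phi = X^2 / (n - p), which rescales
# the coefficient covariance (quasi-likelihood: the score equations are
# unchanged). Model selection uses the quasi-AIC, -2 l / phi + 2 p.

#' Fit a quasi-Poisson log-link regression by IRLS
#'
#' Maximizes the Poisson log-likelihood with log link by iteratively
#' reweighted least squares (deterministic start: all coefficients 0 except
#' the intercept at `log(mean(y) + 0.5/n)`), declaring convergence when the
#' relative deviance change falls below `tol`. The dispersion is the Pearson
#' estimate `phi = sum((y - mu)^2 / mu) / (n - p)`; the coefficient
#' covariance is `phi * (X' W X)^-1` and p-values are two-sided Wald
#' (normal reference).
#'
#' @param y non-negative integer counts, or an `airlag_design` (in which
#'   case `X` is taken from it).
#' @param X design matrix with full column rank, including the intercept.
#' @param tol relative deviance convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return an object of class `"qp_fit"` with elements `coefficients`,
#'   `se`, `zvalue`, `pvalue`, `vcov`, `dispersion`, `deviance`, `loglik`
#'   (Poisson log-likelihood at the fit), `qaic`, `fitted`, `iterations`,
#'   `n`, `p`, and the `design` when one was supplied.
#' @export
qp_fit <- function(y, X = NULL, tol = 1e-9, max_iter = 100L) {
  design <- NULL
  if (inherits(y, "airlag_design")) {
    design <- y
    X <- design$X
    y <- design$y
  }
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (any(!is.finite(y)) || any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop("y must be non-negative integer counts")
  }
  if (n <= p) stop("need more observations than columns (n = ", n, ", p = ", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop("design matrix is rank deficient; offending columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]], collapse = ", "))
  }

  beta <- rep(0, p)
  intercept_col <- which(apply(X, 2, function(col) all(col == 1)))[1]
  eta <- if (!is.na(intercept_col)) {
    beta[intercept_col] <- log(mean(y) + 0.5 / n)
    rep(beta[intercept_col], n)
  } else {
    rep(0, n)
  }
  mu <- exp(eta)
  dev <- poisson_deviance(y, mu)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu
    z <- eta + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    eta_new <- drop(X %*% beta_new)
    # step-halve if the update overshoots into numerical trouble
    step <- 1
    while ((any(!is.finite(exp(eta_new))) ||
            !is.finite(poisson_deviance(y, exp(eta_new)))) && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (fit$coefficients - beta)
      eta_new <- drop(X %*% beta_new)
    }
    beta <- beta_new
    eta <- eta_new
    mu <- exp(eta)
    dev_new <- poisson_deviance(y, mu)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged) {
    stop("IRLS did not converge in ", max_iter,
         " iterations (deviance trace ends at ", format(dev), ")")
  }

  XtWX <- crossprod(X * sqrt(mu))
  XtWX_inv <- chol2inv(chol(XtWX))
  pearson <- sum((y - mu)^2 / mu)
  phi <- pearson / (n - p)
  vcov <- phi * XtWX_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  zval <- beta / se
  ll <- sum(dpois(y, mu, log = TRUE))

  out <- list(
    coefficients = setNames(beta, colnames(X)),
    se = setNames(se, colnames(X)),
    zvalue = setNames(zval, colnames(X)),
    pvalue = setNames(2 * pnorm(-abs(zval)), colnames(X)),
    vcov = vcov, dispersion = phi, pearson = pearson,
    deviance = dev, loglik = ll,
    fitted = mu, iterations = iter, converged = converged,
    n = n, p = p, design = design
  )
  out$qaic <- -2 * ll / phi + 2 * p
  class(out) <- "qp_fit"
  out
}

poisson_deviance <- function(y, mu) {
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf("quasi-Poisson fit: n = %d, p = %d, dispersion = %.3f, qAIC = %.2f (%d IRLS iterations)\n",
              x$n, x$p, x$dispersion, x$qaic, x$iterations))
  invisible(x)
}

#' Coefficient summary of a quasi-Poisson fit
#'
#' @param object a `qp_fit`.
#' @param ... unused.
#' @return a data.frame with one row per term: estimate, SE, z, p.
#' @export
summary.qp_fit <- function(object, ...) {
  data.frame(term = names(object$coefficients),
             estimate = unname(object$coefficients),
             se = unname(object$se),
             z = unname(object$zvalue),
             p_value = unname(object$pvalue),
             row.names = NULL)
}

#' Quasi-AIC of a fit
#'
#' `qaic = -2 * loglik / phi + 2 * p`; with `use_dispersion = FALSE` the
#' dispersion is fixed at 1 and this reduces to the ordinary Poisson AIC.
#'
#' @param fit a `qp_fit`.
#' @param use_dispersion divide the log-likelihood by the Pearson dispersion
#'   (default) or not.
#' @return a number.
#' @export
qaic <- function(fit, use_dispersion = TRUE) {
  stopifnot(inherits(fit, "qp_fit"))
  phi <- if (use_dispersion) fit$dispersion else 1
  if (phi <= 0) stop("non-positive dispersion estimate")
  -2 * fit$loglik / phi + 2 * fit$p
}

#' Select spline degrees of freedom by quasi-AIC
#'
#' Refits the model over candidate df values for the targeted spline —
#' df/year of the time spline, or the df of the temperature or humidity
#' spline — holding everything else fixed, and returns the qAIC-minimizing
#' value; ties are broken toward the smaller df. Candidates whose fit fails
#' are skipped with a warning.
#'
#' @param panel an imputed or complete-case daily panel.
#' @param pollutant exposure pollutant.
#' @param candidates integer df candidates (default 1..10).
#' @param target `"time"`, `"temp"` or `"humidity"`.
#' @param structure a [lag_structure()].
#' @param use_dispersion passed to [qaic()].
#' @param ... further arguments to [assemble_design()].
#' @return the selected df, with the candidate qAIC values as attribute
#'   `"qaic"`.
#' @export
select_df <- function(panel, pollutant, candidates = 1:10,
                      target = c("time", "temp", "humidity"),
                      structure = lag_structure("unconstrained"),
                      use_dispersion = TRUE, ...) {
  target <- match.arg(target)
  if (!length(candidates)) stop("empty candidate set")
  candidates <- sort(unique(as.integer(candidates)))
  scores <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    args <- list(panel = panel, pollutant = pollutant, structure = structure, ...)
    args[[switch(target, time = "df_time_per_year",
                 temp = "df_temp", humidity = "df_humidity")]] <- candidates[i]
    scores[i] <- tryCatch(
      qaic(qp_fit(do.call(assemble_design, args)), use_dispersion),
      error = function(e) {
        warning("candidate df ", candidates[i], " skipped: ", conditionMessage(e))
        NA_real_
      })
  }
  if (all(is.na(scores))) stop("all candidate fits failed")
  best <- candidates[which.min(scores)]  # candidates sorted: ties -> smaller df
  attr(best, "qaic") <- setNames(scores, candidates)
  best
}
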