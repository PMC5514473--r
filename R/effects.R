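# Rate ratios per reporting increment.
#
# Every fitted exposure coefficient beta (per-unit log rate-ratio) is
# reported as RR = exp(beta * increment) with a 95% Wald interval
# exp((beta +/- 1.959964 * se) * increment), per 10 ug/m3 for pollutants in
# ug/m3 and per 1 mg/m3 for CO. By Wald duality, p < 0.05 exactly when the
# 95% interval excludes 1.

Z975 <- qnorm(0.975)  # 1.959964

#' Rate ratio from a fitted coefficient
#'
#' @param beta per-unit log rate-ratio.
#' @param se its standard error (>= 0).
#' @param increment reporting increment on the exposure scale (> 0).
#' @return a one-row data.frame: `rr`, `ci_low`, `ci_high`, `p_value`,
#'   `beta`, `se`, `increment`.
#' @export
rr_from_coef <- function(beta, se, increment) {
  stopifnot(se >= 0, increment > 0)
  p <- if (se > 0) 2 * pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  data.frame(
    rr = exp(beta * increment),
    ci_low = exp((beta - Z975 * se) * increment),
    ci_high = exp((beta + Z975 * se) * increment),
    p_value = p,
    beta = beta, se = se, increment = increment
  )
}

# One tidy row per exposure coefficient of a fit.
effect_rows <- function(fit, stratum, model_label, co_pollutant = NA_character_) {
  design <- fit$design
  stopifnot(!is.null(design))
  cols <- design$blocks$exposure
  lag_map <- design$lag_map
  rows <- list()
  for (i in seq_along(cols)) {
    est <- rr_from_coef(fit$coefficients[cols[i]], fit$se[cols[i]],
                        design$increment)
    lags <- lag_map[[i]]
    # constrained strata are reported at every member lag with the shared value
    for (l in lags) {
      rows[[length(rows) + 1L]] <- data.frame(
        pollutant = design$pollutant, stratum = stratum, model = model_label,
        lag = l,
        lag_stratum = if (length(lags) == 1) as.character(lags)
                      else paste0(min(lags), "-", max(lags)),
        co_pollutant = co_pollutant, est, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$lag), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("airlag_effects", class(out))
  out
}

bind_effects <- function(lst) {
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  class(out) <- unique(c("airlag_effects", class(out)))
  out
}

#' Single-lag models, one lag at a time
#'
#' Fits eight separate models, each containing the exposure at exactly one
#' lag 0..7 together with the full confounder blocks, and reports the rate
#' ratio per reporting increment at each lag.
#'
#' @param panel an imputed or complete-case daily panel.
#' @param pollutant exposure pollutant.
#' @param lags lags to fit (default 0:7).
#' @param outcome count column (default `"all"`; also sets the stratum
#'   label).
#' @param ... further arguments to [assemble_design()].
#' @return an `airlag_effects` data.frame, one row per lag.
#' @export
run_single_lag_suite <- function(panel, pollutant, lags = 0:7,
                                 outcome = "all", ...) {
  max_lag <- max(lags)
  res <- lapply(lags, function(l) {
    st <- lag_structure("single", max_lag = max_lag, lag = l)
    fit <- tryCatch(
      qp_fit(assemble_design(panel, pollutant, st, outcome = outcome, ...)),
      error = function(e) stop("single-lag model at lag ", l, " failed: ",
                               conditionMessage(e), call. = FALSE))
    effect_rows(fit, stratum = outcome, model_label = "single")
  })
  bind_effects(res)
}

#' Distributed-lag model over lags 0..7
#'
#' One model containing all lags simultaneously. Unconstrained: a free
#' coefficient per lag. Constrained: one shared coefficient per lag stratum
#' (default strata `{0}, {1,2}, {3..7}`), reported at every member lag with
#' identical values.
#'
#' @param panel an imputed or complete-case daily panel.
#' @param pollutant exposure pollutant.
#' @param mode `"unconstrained"` or `"constrained"`.
#' @param strata lag strata for the constrained model.
#' @param outcome count column.
#' @param max_lag largest lag.
#' @param ... further arguments to [assemble_design()].
#' @return an `airlag_effects` data.frame, one row per lag.
#' @export
run_dlm_suite <- function(panel, pollutant,
                          mode = c("unconstrained", "constrained"),
                          strata = list(0L, 1:2, 3:7), outcome = "all",
                          max_lag = 7L, ...) {
  mode <- match.arg(mode)
  st <- if (mode == "constrained") {
    lag_structure("constrained", max_lag = max_lag, strata = strata)
  } else {
    lag_structure("unconstrained", max_lag = max_lag)
  }
  fit <- qp_fit(assemble_design(panel, pollutant, st, outcome = outcome, ...))
  effect_rows(fit, stratum = outcome, model_label = mode)
}

#' Subgroup analyses by sex and age
#'
#' Re-runs the requested suite with the outcome replaced by each stratum
#' count (confounders unchanged) and labels the strata in the output.
#'
#' @param panel an imputed or complete-case daily panel.
#' @param pollutant exposure pollutant.
#' @param strata stratum count columns (default male, female, under60,
#'   over60; `"all"` reproduces the unstratified run).
#' @param suite `"single"`, `"unconstrained"` or `"constrained"`.
#' @param ... further arguments to the suite function.
#' @return an `airlag_effects` data.frame.
#' @export
run_subgroups <- function(panel, pollutant,
                          strata = c("male", "female", "under60", "over60"),
                          suite = c("single", "unconstrained", "constrained"),
                          ...) {
  suite <- match.arg(suite)
  res <- lapply(strata, function(s) {
    if (!s %in% names(panel)) stop("stratum column '", s, "' not in panel")
    if (all(panel[[s]] == 0, na.rm = TRUE)) {
      stop("stratum '", s, "' has all-zero counts")
    }
    if (suite == "single") {
      run_single_lag_suite(panel, pollutant, outcome = s, ...)
    } else {
      run_dlm_suite(panel, pollutant, mode = suite, outcome = s, ...)
    }
  })
  bind_effects(res)
}

#' Two-pollutant model
#'
#' Single-lag-0 model for `pollutant` with the co-pollutant's same-day
#' concentration added as one linear column; reports the primary
#' pollutant's increment rate ratio adjusted for the co-pollutant.
#'
#' @param panel an imputed or complete-case daily panel.
#' @param pollutant primary pollutant.
#' @param co_pollutant adjustment pollutant (must differ).
#' @param outcome count column.
#' @param ... further arguments to [assemble_design()].
#' @return a one-row `airlag_effects` data.frame.
#' @export
run_two_pollutant <- function(panel, pollutant, co_pollutant,
                              outcome = "all", ...) {
  if (identical(pollutant, co_pollutant)) {
    stop("co_pollutant must differ from pollutant")
  }
  st <- lag_structure("single", max_lag = 0L, lag = 0L)
  fit <- qp_fit(assemble_design(panel, pollutant, st, outcome = outcome,
                                second_pollutant = co_pollutant, ...))
  effect_rows(fit, stratum = outcome, model_label = "two_pollutant",
              co_pollutant = co_pollutant)
}

#' Format effect estimates in table style
#'
#' Human-readable "RR (95% CI), p" rendering with 2-4 significant decimals;
#' machine outputs (the data.frame itself) keep full precision.
#'
#' @param effects an `airlag_effects` data.frame.
#' @param digits significant digits for the RR and CI.
#' @return a data.frame of formatted strings.
#' @export
format_effects <- function(effects, digits = 3) {
  data.frame(
    pollutant = effects$pollutant, stratum = effects$stratum,
    model = effects$model, lag = effects$lag,
    rr_ci = sprintf("%s (%s-%s)",
                    signif(effects$rr, digits + 1),
                    signif(effects$ci_low, digits + 1),
                    signif(effects$ci_high, digits + 1)),
    p = signif(effects$p_value, 2)
  )
}

#' Forest-style plot of lag-specific rate ratios
#'
#' Lag on the horizontal axis, RR with 95% CI bars on the vertical axis,
#' faceted by model variant and stratum, with a reference line at RR = 1.
#'
#' @param effects an `airlag_effects` data.frame.
#' @return a ggplot object.
#' @export
plot_effects <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = lag, y = rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_low, ymax = ci_high)) +
    ggplot2::facet_grid(stratum ~ pollutant + model) +
    ggplot2::labs(x = "lag (days)",
                  y = "rate ratio per reporting increment") +
    ggplot2::theme_bw()
}
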