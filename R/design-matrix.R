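# Covariate blocks of the admission model
#
#   log mu(t) = a + sum_l beta_l AP(t - l) + s(time, 7 df/year)
#               + s(T, 4 df) + s(H, 4 df) + gamma DOW
#
# Exposure enters linearly on its measurement scale through one of three
# lag bases (single-lag, unconstrained, lag-stratified constrained); the
# long-term/seasonal trend, temperature and humidity enter through natural
# cubic splines; day-of-week through indicator terms (or days since the
# most recent holiday).

#' Lag structure of the exposure basis
#'
#' @param mode `"single"` (one lag at a time), `"unconstrained"` (a free
#'   coefficient per lag 0..`max_lag`) or `"constrained"` (one shared
#'   coefficient per lag stratum).
#' @param max_lag largest lag in days (default 7).
#' @param lag the single lag used when `mode = "single"`.
#' @param strata ordered list of integer vectors partitioning `0:max_lag`
#'   (default `{0}, {1,2}, {3..7}`), used when `mode = "constrained"`.
#' @return a list of class `"lag_structure"`.
#' @export
lag_structure <- function(mode = c("unconstrained", "single", "constrained"),
                          max_lag = 7L, lag = NULL,
                          strata = list(0L, 1:2, 3:7)) {
  mode <- match.arg(mode)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0) stop("max_lag must be >= 0")
  if (mode == "single") {
    if (is.null(lag)) stop("mode 'single' requires a lag")
    lag <- as.integer(lag)
    if (lag < 0 || lag > max_lag) stop("single-lag 'lag' must lie in [0, max_lag]")
  } else if (!is.null(lag)) {
    stop("'lag' is only meaningful with mode 'single'")
  }
  if (mode == "constrained") {
    flat <- sort(unlist(strata))
    if (!identical(as.integer(flat), 0:max_lag)) {
      stop("strata must partition 0..max_lag without overlap")
    }
  }
  structure(list(mode = mode, max_lag = max_lag, lag = lag,
                 strata = lapply(strata, as.integer)),
            class = "lag_structure")
}

#' Natural cubic spline basis with df columns
#'
#' Returns an `n x df` basis whose span, together with the intercept, is the
#' space of natural cubic splines (linear beyond the boundary knots) with
#' interior knots at equally spaced quantiles of `x` and boundary knots at
#' the observed range. With `df = 1` the natural constraints leave only the
#' linear term.
#'
#' @param x numeric vector with at least `df + 1` distinct values.
#' @param df basis dimension (>= 1).
#' @return an `n x df` matrix; the knots and the generating [splines::ns()]
#'   attributes are attached so the basis can be re-evaluated at new points
#'   with [predict_basis()].
#' @export
natural_cubic_basis <- function(x, df) {
  df <- as.integer(df)
  if (df < 1) stop("df must be >= 1")
  if (length(unique(x)) < df + 1) {
    stop("x has too few distinct values (", length(unique(x)),
         ") for df = ", df)
  }
  B <- splines::ns(x, df = df)
  stopifnot(ncol(B) == df)
  B
}

#' Re-evaluate a natural cubic spline basis at new points
#'
#' @param basis a basis from [natural_cubic_basis()].
#' @param newx points at which to evaluate (may lie beyond the boundary
#'   knots, where the basis functions continue linearly).
#' @return a `length(newx) x df` matrix.
#' @export
predict_basis <- function(basis, newx) {
  predict(basis, newx)
}

#' Natural cubic spline of calendar time
#'
#' The total degrees of freedom are `round(df_per_year * span / 365.25)`
#' where `span` is the number of calendar days covered (so 2191 days at
#' 7 df/year give 42 columns), and the basis is built on the numeric day
#' index — calendar gaps (e.g. after complete-case filtering) are respected.
#'
#' @param dates a `Date` vector.
#' @param df_per_year degrees of freedom per 365.25-day year.
#' @return the basis matrix, with the chosen total df as attribute
#'   `"df_total"`.
#' @export
time_spline <- function(dates, df_per_year = 7) {
  if (df_per_year < 1) stop("df_per_year must be >= 1")
  span <- as.numeric(max(dates) - min(dates)) + 1
  df_total <- as.integer(round(df_per_year * span / 365.25))
  if (df_total < 1) {
    stop("time span (", span, " days) too short for df_per_year = ", df_per_year)
  }
  B <- natural_cubic_basis(as.numeric(dates), df_total)
  attr(B, "df_total") <- df_total
  B
}

#' Lagged-exposure basis
#'
#' Builds the exposure columns for the three model variants: `single` gives
#' the one column `x(t - lag)`; `unconstrained` gives `max_lag + 1` columns
#' `x(t), ..., x(t - max_lag)`; `constrained` gives one column per lag
#' stratum equal to the sum of `x(t - l)` over the lags `l` in the stratum,
#' so the stratum coefficient is the shared per-unit log rate-ratio at each
#' member lag. Lags are taken on calendar time when `dates` are supplied
#' (days absent from the series yield `NA`), otherwise on position. Rows
#' with any undefined lag are `NA` and flagged via `attr(, "complete_row")`.
#'
#' @param x exposure series (no missing values; impute or filter first).
#' @param structure a [lag_structure()].
#' @param dates optional `Date` vector aligned with `x` for calendar lags.
#' @return a matrix with attributes `lag_map` (list: the lags behind each
#'   column) and `complete_row` (logical).
#' @export
lag_basis <- function(x, structure, dates = NULL) {
  stopifnot(inherits(structure, "lag_structure"))
  if (anyNA(x)) stop("exposure has missing values; impute or filter first")
  n <- length(x)
  L <- structure$max_lag
  lagged <- matrix(NA_real_, n, L + 1)
  if (is.null(dates)) {
    for (l in 0:L) if (l < n) lagged[(l + 1):n, l + 1] <- x[1:(n - l)]
  } else {
    idx <- match(as.numeric(dates) - rep(0:L, each = n),
                 as.numeric(dates))
    lagged <- matrix(x[idx], n, L + 1)
  }
  colnames(lagged) <- paste0("lag", 0:L)
  lag_sets <- switch(structure$mode,
    single = list(structure$lag),
    unconstrained = as.list(0:L),
    constrained = structure$strata
  )
  B <- vapply(lag_sets, function(ls) rowSums(lagged[, ls + 1, drop = FALSE]),
              numeric(n))
  colnames(B) <- vapply(lag_sets, function(ls) {
    if (length(ls) == 1) paste0("lag", ls) else paste0("lag", min(ls), "_", max(ls))
  }, character(1))
  attr(B, "lag_map") <- lag_sets
  used <- sort(unique(unlist(lag_sets))) + 1L
  attr(B, "complete_row") <- stats::complete.cases(lagged[, used, drop = FALSE])
  B
}

#' Day-of-week terms
#'
#' Default mode: six indicator columns for day-of-week with Saturday (the
#' first day of the Iranian week) as the reference. Alternate mode
#' `"days_since_holiday"`: a single integer column counting days elapsed
#' since the most recent holiday in the supplied calendar.
#'
#' @param dates a `Date` vector.
#' @param mode `"indicators"` or `"days_since_holiday"`.
#' @param holidays a `Date` vector of holidays (required for the alternate
#'   mode; there must be a holiday on or before the first date).
#' @return a matrix of day-of-week terms.
#' @export
dow_terms <- function(dates, mode = c("indicators", "days_since_holiday"),
                      holidays = NULL) {
  mode <- match.arg(mode)
  if (mode == "indicators") {
    wd <- as.POSIXlt(dates)$wday  # 0 = Sunday ... 6 = Saturday
    lev <- c(6, 0:5)              # Saturday first (reference)
    f <- factor(wd, levels = lev,
                labels = c("sat", "sun", "mon", "tue", "wed", "thu", "fri"))
    M <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(M) <- paste0("dow_", levels(f)[-1])
    rownames(M) <- NULL
    M
  } else {
    if (is.null(holidays)) {
      stop("mode 'days_since_holiday' requires a holiday calendar")
    }
    holidays <- sort(as.Date(holidays))
    idx <- findInterval(as.numeric(dates), as.numeric(holidays))
    if (any(idx == 0)) stop("no holiday on or before the first date")
    M <- matrix(as.numeric(dates) - as.numeric(holidays[idx]), ncol = 1,
                dimnames = list(NULL, "days_since_holiday"))
    M
  }
}

#' Assemble the full design matrix
#'
#' Concatenates the intercept, the lagged-exposure basis for `pollutant`,
#' the calendar-time spline, temperature and humidity splines, the
#' day-of-week block and (optionally) a co-pollutant's same-day
#' concentration as one linear column. Burn-in rows, rows with undefined
#' lags and rows with a missing outcome are dropped and recorded. CO is
#' carried in mg/m3 and all other pollutants in ug/m3; reporting increments
#' are applied downstream.
#'
#' @param panel an imputed or complete-case daily panel.
#' @param pollutant exposure pollutant name.
#' @param structure a [lag_structure()].
#' @param outcome count column used as the response (default `"all"`).
#' @param df_time_per_year df/year of the time spline; `0` omits the time
#'   spline entirely (for diagnostics of confounder control).
#' @param df_temp,df_humidity df of the weather splines.
#' @param dow_mode,holidays passed to [dow_terms()].
#' @param second_pollutant optional co-pollutant added at lag 0 as a linear
#'   column (two-pollutant models).
#' @return an object of class `"airlag_design"`: the matrix `X`, the
#'   response `y`, `dates`, named `blocks` (column indices per block),
#'   `lag_map`, `pollutant`, `increment` and `outcome`.
#' @export
assemble_design <- function(panel, pollutant,
                            structure = lag_structure("unconstrained"),
                            outcome = "all",
                            df_time_per_year = 7,
                            df_temp = 4, df_humidity = 4,
                            dow_mode = "indicators", holidays = NULL,
                            second_pollutant = NULL) {
  pollutant <- match.arg(pollutant, POLLUTANTS)
  if (!outcome %in% names(panel)) stop("outcome column '", outcome, "' not in panel")
  for (v in c(pollutant, second_pollutant, "temp", "humidity")) {
    if (anyNA(panel[[v]])) {
      stop("missing values in required column '", v, "' (first at row ",
           which(is.na(panel[[v]]))[1], "); impute or filter first")
    }
  }
  if (!is.null(second_pollutant)) {
    second_pollutant <- match.arg(second_pollutant, POLLUTANTS)
    if (second_pollutant == pollutant) {
      stop("second_pollutant must differ from pollutant")
    }
  }

  expo <- lag_basis(panel[[pollutant]], structure, dates = panel$date)
  keep <- attr(expo, "complete_row") & !is.na(panel[[outcome]])
  if ("burn_in" %in% names(panel)) keep <- keep & !panel$burn_in
  if (sum(keep) == 0) stop("no usable rows after lag/burn-in exclusions")
  dates <- panel$date[keep]

  blocks <- list()
  X <- matrix(1, sum(keep), 1, dimnames = list(NULL, "(Intercept)"))
  blocks$intercept <- 1L

  Xe <- expo[keep, , drop = FALSE]
  blocks$exposure <- ncol(X) + seq_len(ncol(Xe))
  X <- cbind(X, Xe)

  if (df_time_per_year > 0) {
    Bt <- time_spline(dates, df_time_per_year)
    colnames(Bt) <- paste0("time_ns", seq_len(ncol(Bt)))
    blocks$time <- ncol(X) + seq_len(ncol(Bt))
    X <- cbind(X, Bt)
  }

  Btemp <- natural_cubic_basis(panel$temp[keep], df_temp)
  colnames(Btemp) <- paste0("temp_ns", seq_len(df_temp))
  blocks$temp <- ncol(X) + seq_len(df_temp)
  X <- cbind(X, Btemp)

  Bhum <- natural_cubic_basis(panel$humidity[keep], df_humidity)
  colnames(Bhum) <- paste0("humidity_ns", seq_len(df_humidity))
  blocks$humidity <- ncol(X) + seq_len(df_humidity)
  X <- cbind(X, Bhum)

  Bdow <- dow_terms(dates, dow_mode, holidays)
  blocks$dow <- ncol(X) + seq_len(ncol(Bdow))
  X <- cbind(X, Bdow)

  if (!is.null(second_pollutant)) {
    co_col <- matrix(panel[[second_pollutant]][keep], ncol = 1,
                     dimnames = list(NULL, paste0("co_", second_pollutant)))
    blocks$co_pollutant <- ncol(X) + 1L
    X <- cbind(X, co_col)
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("design matrix is rank deficient; collinear columns: ",
            paste(dropped, collapse = ", "))
  }

  structure(list(
    X = X, y = panel[[outcome]][keep], dates = dates, blocks = blocks,
    lag_map = attr(expo, "lag_map"), pollutant = pollutant,
    second_pollutant = second_pollutant,
    increment = reporting_increment(pollutant),
    outcome = outcome, lag_structure = structure
  ), class = "airlag_design")
}

#' @export
print.airlag_design <- function(x, ...) {
  cat("airlag design:", nrow(x$X), "days x", ncol(x$X), "columns;",
      "exposure", x$pollutant, paste0("(", x$lag_structure$mode, ")"),
      "outcome", x$outcome, "\n")
  cat("blocks:", paste(sprintf("%s[%d]", names(x$blocks),
                               lengths(x$blocks)), collapse = " "), "\n")
  invisible(x)
}

#' Export a design matrix with a column-metadata sidecar
#'
#' Writes the matrix as CSV and a JSON sidecar mapping each column to its
#' block and (for exposure columns) its lag set, for audit.
#'
#' @param design an `airlag_design`.
#' @param path CSV path; the sidecar is written at `paste0(path, ".meta.json")`.
#' @export
write_design <- function(design, path) {
  df <- data.frame(date = design$dates, y = design$y, design$X,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- list(
    blocks = lapply(design$blocks, function(ix) colnames(design$X)[ix]),
    lag_map = design$lag_map,
    pollutant = design$pollutant,
    outcome = design$outcome
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
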