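# Daily-panel conventions shared across the package.
#
# A daily panel is a data.frame with one row per calendar day:
#   date      Date, consecutive (complete-case filtering may leave gaps)
#   co        carbon monoxide, mg/m3
#   so2, no2, o3, pm25, pm10   ug/m3
#   temp      daily mean temperature, degrees C
#   humidity  daily mean relative humidity, %
#   all, male, female, under60, over60   admission counts (non-negative ints)
#   burn_in   logical; lead days generated only to supply lagged exposures

POLLUTANTS <- c("co", "so2", "no2", "o3", "pm25", "pm10")

POLLUTANT_UNITS <- c(
  co = "mg/m3", so2 = "ug/m3", no2 = "ug/m3",
  o3 = "ug/m3", pm25 = "ug/m3", pm10 = "ug/m3"
)

COUNT_COLS <- c("all", "male", "female", "under60", "over60")

#' Reporting increment for a pollutant
#'
#' Effects are reported per 10 ug/m3 for pollutants measured in ug/m3 and
#' per 1 mg/m3 for CO (which is carried in mg/m3 throughout).
#'
#' @param pollutant one of `"co"`, `"so2"`, `"no2"`, `"o3"`, `"pm25"`,
#'   `"pm10"`.
#' @return the increment on the pollutant's own measurement scale.
#' @export
reporting_increment <- function(pollutant) {
  pollutant <- match.arg(pollutant, POLLUTANTS)
  if (pollutant == "co") 1 else 10
}

# Internal: check the structural invariants of a daily panel.
validate_panel <- function(panel, require_complete = FALSE) {
  stopifnot(is.data.frame(panel))
  needed <- c("date", POLLUTANTS)
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$date)) stop("panel has duplicated dates")
  if (is.unsorted(panel$date)) stop("panel dates must be increasing")
  for (cc in intersect(COUNT_COLS, names(panel))) {
    v <- panel[[cc]]
    bad <- !is.na(v) & (v < 0 | abs(v - round(v)) > 1e-8)
    if (any(bad)) stop("count column '", cc, "' has negative or non-integer values")
  }
  if (all(c("all", "male", "female") %in% names(panel))) {
    ok <- is.na(panel$all) | is.na(panel$male) | is.na(panel$female) |
      (panel$male + panel$female == panel$all)
    if (!all(ok)) stop("male + female counts do not sum to 'all'")
  }
  if (require_complete && anyNA(panel[POLLUTANTS])) {
    stop("panel has missing pollutant values; impute or filter first")
  }
  neg <- vapply(POLLUTANTS, function(p) any(panel[[p]] < 0, na.rm = TRUE), logical(1))
  if (any(neg)) {
    warning("negative pollutant concentrations in: ",
            paste(POLLUTANTS[neg], collapse = ", "))
  }
  invisible(panel)
}

#' Write / read a daily panel as CSV
#'
#' Panels are stored as plain CSV with ISO-8601 dates and missing values as
#' empty fields, so they round-trip through any spreadsheet or language.
#'
#' @param panel a daily panel data.frame.
#' @param path file path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   the panel with `date` parsed as `Date`.
#' @export
write_panel <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  panel <- read.csv(path, stringsAsFactors = FALSE)
  panel$date <- as.Date(panel$date)
  if ("burn_in" %in% names(panel)) panel$burn_in <- as.logical(panel$burn_in)
  validate_panel(panel)
  panel
}

#' Write / read a station-level panel as CSV
#'
#' One row per (date, station); pollutant fields may be empty (missing).
#'
#' @param stations a station panel as returned by [split_stations()].
#' @param path file path.
#' @export
write_stations <- function(stations, path) {
  write.csv(stations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_stations
#' @export
read_stations <- function(path) {
  st <- read.csv(path, stringsAsFactors = FALSE)
  st$date <- as.Date(st$date)
  st
}
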