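#' Daily weather series for one location
#'
#' Container for daily maximum/minimum temperature (degC) and precipitation
#' (mm) over a run of 365-day calendar years (leap days are dropped
#' upstream). Each element is a 365 x n_years matrix with days in rows.
#'
#' @param tmax,tmin,prcp numeric 365 x n_years matrices (or vectors for a
#'   single year). `tmax >= tmin` must hold elementwise and `prcp >= 0`.
#' @param years integer vector of year labels, one per column.
#' @return An object of class `daily_series`.
#' @examples
#' s <- daily_series(matrix(20, 365, 2), matrix(10, 365, 2),
#'                   matrix(2, 365, 2), years = 2001:2002)
#' annual_gdd(s, 2001)
#' @export
daily_series <- function(tmax, tmin, prcp, years) {
  tmax <- as.matrix(tmax); tmin <- as.matrix(tmin); prcp <- as.matrix(prcp)
  if (nrow(tmax) != 365L) stop("daily_series expects 365-day years")
  if (!identical(dim(tmax), dim(tmin)) || !identical(dim(tmax), dim(prcp))) {
    stop("tmax, tmin and prcp must have identical dimensions")
  }
  years <- as.integer(years)
  if (length(years) != ncol(tmax)) stop("one year label per column required")
  if (anyNA(tmax) || anyNA(tmin) || anyNA(prcp)) stop("missing days")
  if (any(tmax < tmin)) stop("tmax < tmin encountered")
  if (any(prcp < 0)) stop("negative precipitation encountered")
  structure(list(tmax = tmax, tmin = tmin, prcp = prcp, years = years),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %d year(s): %s\n", length(x$years),
              paste(range(x$years), collapse = "-")))
  invisible(x)
}

year_col <- function(series, year) {
  i <- match(as.integer(year), series$years)
  if (is.na(i)) stop(sprintf("year %s not present in series", year))
  i
}
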