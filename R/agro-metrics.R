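#' Daily growing degree days
#'
#' Clipped-average GDD: both temperatures are clipped into
#' `[gdd_base, gdd_upper]`, averaged, and the base is subtracted (floored at
#' zero). One unit is exposure to 1 degC above base for one day.
#'
#' @param tmax,tmin daily maximum/minimum temperature, degC (vectorized).
#' @param thresholds a [metric_thresholds()] object.
#' @return GDD in degC-day, same length as the inputs.
#' @examples
#' daily_gdd(20, 10)  # 15
#' daily_gdd(35, 10)  # (29.44 + 10)/2 = 19.72
#' @export
daily_gdd <- function(tmax, tmin, thresholds = metric_thresholds()) {
  if (any(tmax < tmin)) stop("tmax < tmin")
  hi <- pmin(pmax(tmax, thresholds$gdd_base), thresholds$gdd_upper)
  lo <- pmin(pmax(tmin, thresholds$gdd_base), thresholds$gdd_upper)
  pmax(0, (hi + lo) / 2 - thresholds$gdd_base)
}

#' Annual growing degree days
#'
#' Sum of [daily_gdd()] over one calendar year of a [daily_series()].
#'
#' @param series a [daily_series()].
#' @param year calendar year present in `series`.
#' @inheritParams daily_gdd
#' @return annual GDD, degC-day.
#' @export
annual_gdd <- function(series, year, thresholds = metric_thresholds()) {
  i <- year_col(series, year)
  sum(daily_gdd(series$tmax[, i], series$tmin[, i], thresholds))
}

#' Frost-free production season length
#'
#' Length of the longest run of consecutive days within the calendar year
#' whose daily minimum stays above the frost threshold. No wraparound
#' across year boundaries.
#'
#' @inheritParams annual_gdd
#' @return season length in days, in `[0, 365]`.
#' @export
frost_free_season_length <- function(series, year,
                                     thresholds = metric_thresholds()) {
  i <- year_col(series, year)
  longest_run(series$tmin[, i] > thresholds$frost_threshold)
}

longest_run <- function(flag) {
  r <- rle(flag)
  w <- r$values
  if (!any(w)) return(0L)
  max(r$lengths[w])
}

#' Sine-curve hourly temperature disaggregation
#'
#' Estimates the 24 hourly temperatures of a day from its extremes with a
#' single sine curve that peaks at 15:00 and bottoms at 03:00:
#' `T(h) = (tmax+tmin)/2 + (tmax-tmin)/2 * sin(2*pi*(h-9)/24)`, `h = 0..23`.
#' The 24-hour mean equals `(tmax+tmin)/2` exactly and all values stay in
#' `[tmin, tmax]`.
#'
#' @param tmax,tmin daily extremes, degC (scalars).
#' @return numeric vector of 24 hourly temperatures (hours 0-23).
#' @export
disaggregate_hourly <- function(tmax, tmin) {
  if (any(tmax < tmin)) stop("tmax < tmin")
  h <- 0:23
  (tmax + tmin) / 2 + (tmax - tmin) / 2 * sin(2 * pi * (h - 9) / 24)
}

# sin() factors shared by the vectorized hourly metrics
HOUR_SINE <- sin(2 * pi * ((0:23) - 9) / 24)

#' Heat degree hours over the summer block
#'
#' Accumulated hourly exceedance above the heat threshold over the Jul-Sep
#' (JAS) season, with hourly temperatures from [disaggregate_hourly()].
#' One unit is exposure to 1 degC above threshold for one hour.
#'
#' @inheritParams annual_gdd
#' @return heat degree hours, degC-hour.
#' @export
heat_degree_hours <- function(series, year,
                              thresholds = metric_thresholds()) {
  i <- year_col(series, year)
  d <- SEASON_DAYS$jas
  hourly_exceedance_sum(series$tmax[d, i], series$tmin[d, i],
                        thresholds$heat_threshold)
}

hourly_exceedance_sum <- function(tmax, tmin, thr) {
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  tot <- 0
  for (s in HOUR_SINE) tot <- tot + sum(pmax(0, m + a * s - thr))
  tot
}

#' Chill hours over the dormancy season
#'
#' Number of hours with temperature inside the inclusive
#' `[chill_low, chill_high]` band between Oct 1 of the prior year and Mar 31
#' of `year`, using [disaggregate_hourly()] temperatures. The first year of
#' a series has no prior Oct-Dec: the season is skipped with a warning and
#' `NA` is returned.
#'
#' @inheritParams annual_gdd
#' @return chill hours (0 to 24 x 182), or `NA` for an incomplete season.
#' @export
chill_hours <- function(series, year, thresholds = metric_thresholds()) {
  i <- year_col(series, year)
  if (i == 1L) {
    warning(sprintf(
      "chill season for year %s incomplete (no prior Oct-Dec); skipped",
      year))
    return(NA_real_)
  }
  tx <- c(series$tmax[CHILL_PRIOR_DAYS, i - 1L],
          series$tmax[CHILL_CURRENT_DAYS, i])
  tn <- c(series$tmin[CHILL_PRIOR_DAYS, i - 1L],
          series$tmin[CHILL_CURRENT_DAYS, i])
  hourly_band_count(tx, tn, thresholds$chill_low, thresholds$chill_high)
}

hourly_band_count <- function(tmax, tmin, lo, hi) {
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  tot <- 0
  for (s in HOUR_SINE) {
    t <- m + a * s
    tot <- tot + sum(t >= lo & t <= hi)
  }
  tot
}

#' Precipitation uniformity (wettest minus driest month)
#'
#' The difference between the wettest and driest monthly precipitation
#' totals of the calendar year. Separates winter-wet (large range) from
#' uniform-rain (small range) regimes, in the spirit of the Koppen
#' classification.
#'
#' @inheritParams annual_gdd
#' @return monthly precipitation range, mm.
#' @export
precipitation_uniformity <- function(series, year) {
  i <- year_col(series, year)
  m <- rowsum(series$prcp[, i], DAY_MONTH)
  max(m) - min(m)
}

#' Generic seasonal climate vector
#'
#' Mean temperature (`(tmax+tmin)/2`) and total precipitation for each of
#' the four 3-month blocks JFM / AMJ / JAS / OND: 8 values.
#'
#' @inheritParams annual_gdd
#' @return named numeric vector of length 8.
#' @export
generic_vector <- function(series, year) {
  i <- year_col(series, year)
  tm <- (series$tmax[, i] + series$tmin[, i]) / 2
  pr <- series$prcp[, i]
  out <- c(
    vapply(SEASON_DAYS, function(d) mean(tm[d]), numeric(1)),
    vapply(SEASON_DAYS, function(d) sum(pr[d]), numeric(1))
  )
  setNames(out, GENERIC_VARS)
}

#' Context-specific climate vector
#'
#' The five crop-production-relevant annual values: growing degree days,
#' frost-free season length, summer heat degree hours, chill hours, and the
#' wettest-driest monthly precipitation range. The first year of a series
#' has an incomplete chill season and is rejected.
#'
#' @inheritParams annual_gdd
#' @return named numeric vector of length 5.
#' @export
context_vector <- function(series, year, thresholds = metric_thresholds()) {
  i <- year_col(series, year)
  if (i == 1L) {
    stop(sprintf(
      "context vector for year %s rejected: chill season incomplete", year))
  }
  out <- c(
    annual_gdd(series, year, thresholds),
    frost_free_season_length(series, year, thresholds),
    heat_degree_hours(series, year, thresholds),
    chill_hours(series, year, thresholds),
    precipitation_uniformity(series, year)
  )
  setNames(out, CONTEXT_VARS)
}
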