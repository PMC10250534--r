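#' Agro-climatic metric thresholds
#'
#' Bundle of the temperature thresholds that define the context-specific
#' indices. Defaults are the generic specialty-crop values: growing degree
#' days accumulate between a 0 degC base and a 29.44 degC (85 degF) upper
#' cutoff; heat degree hours count hourly exceedance above 32 degC
#' (89.6 degF) during the summer (Jul-Sep) block; chill hours count hours in
#' the 0-7.22 degC (32-45 degF) band over the Oct 1 (prior year) - Mar 31
#' dormancy season; frost means a daily minimum at or below 0 degC.
#'
#' @param gdd_base GDD base temperature, degC.
#' @param gdd_upper GDD upper cutoff, degC; must exceed `gdd_base`.
#' @param heat_threshold hourly heat-stress threshold, degC.
#' @param chill_low,chill_high inclusive chill band bounds, degC.
#' @param frost_threshold daily-minimum frost threshold, degC.
#' @return An object of class `metric_thresholds`.
#' @examples
#' metric_thresholds()
#' @export
metric_thresholds <- function(gdd_base = 0, gdd_upper = 29.44,
                              heat_threshold = 32,
                              chill_low = 0, chill_high = 7.22,
                              frost_threshold = 0) {
  vals <- c(gdd_base, gdd_upper, heat_threshold, chill_low, chill_high,
            frost_threshold)
  if (!all(is.finite(vals))) {
    stop("all thresholds must be finite numbers")
  }
  if (gdd_base >= gdd_upper) stop("gdd_base must be < gdd_upper")
  if (chill_low >= chill_high) stop("chill_low must be < chill_high")
  structure(
    list(gdd_base = gdd_base, gdd_upper = gdd_upper,
         heat_threshold = heat_threshold,
         chill_low = chill_low, chill_high = chill_high,
         frost_threshold = frost_threshold),
    class = "metric_thresholds"
  )
}
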