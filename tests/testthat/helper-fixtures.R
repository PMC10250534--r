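# Shared fixtures: all synthetic, built in code at test time.

# Small but fully featured world: 6x6 grid, 6 counties (one per row),
# 8 historical + 4 future years, 2 pseudo-GCMs.
tiny_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, grid_shape = c(6, 6), n_counties = 6,
                   n_years_hist = 8, n_years_future = 4, n_gcms = 2, ...)
}

# Deterministic limit: no noise of any kind, optionally no warming.
zero_cfg <- function(seed = 1, warming = FALSE, ...) {
  args <- list(seed = seed, sd_day = 0, sd_year = 0, precip_shape = Inf,
               precip_sd_year = 0, suppressed_fraction = 0, ...)
  if (!warming) args$warming_offsets <- matrix(0, 2, 2)
  if (is.null(args$grid_shape)) args$grid_shape <- c(6, 6)
  if (is.null(args$n_counties)) args$n_counties <- 6
  if (is.null(args$n_years_hist)) args$n_years_hist <- 5
  if (is.null(args$n_years_future)) args$n_years_future <- 3
  if (is.null(args$n_gcms)) args$n_gcms <- 2
  do.call(synthetic_config, args)
}

# Constant-weather daily series.
const_series <- function(tmax = 20, tmin = 10, prcp = 2, ny = 2,
                         start_year = 2001) {
  daily_series(matrix(tmax, 365, ny), matrix(tmin, 365, ny),
               matrix(prcp, 365, ny), years = start_year + seq_len(ny) - 1)
}

# Daily precipitation vector realizing given monthly totals (uniform
# within each month).
monthly_precip_days <- function(totals) {
  month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  unlist(lapply(1:12, function(m) rep(totals[m] / month_days[m],
                                      month_days[m])))
}

# Independent hour-by-hour oracle for the sine disaggregation, written
# out directly from the curve definition (peak 15:00, trough 03:00).
oracle_hourly <- function(tmax, tmin) {
  sapply(0:23, function(h) {
    (tmax + tmin) / 2 + (tmax - tmin) / 2 * sin(2 * pi * (h - 9) / 24)
  })
}
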