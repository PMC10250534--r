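#' Configuration of the synthetic climate/census world
#'
#' Describes a seeded synthetic dataset that emulates the statistical
#' structure of the real inputs: gridded daily Tmax/Tmin/precip with a
#' north-south temperature gradient (the row index plays latitude's role),
#' two precipitation regimes split along columns (winter-wet west vs
#' uniform east), grid-shared interannual (year) effects plus per-cell
#' day-level Gaussian noise, a pseudo-GCM future ensemble defined by
#' per-GCM/scenario warming offsets, a land-use (agricultural fraction)
#' field, a contiguous grid-to-county partition with region labels, and a
#' county crop census with heavy-tailed specialty acreage.
#'
#' @param seed integer; fully determines every output.
#' @param grid_shape integer `(rows, cols)` of the cell grid.
#' @param n_counties number of counties; at most `prod(grid_shape)`.
#' @param n_years_hist historical years (>= 3; default 30, 1991-2020).
#' @param n_years_future future-period years per GCM (default 10; only the
#'   future normal is ever used downstream, never a future ICV).
#' @param n_gcms pseudo-GCM ensemble size (default 6).
#' @param scenarios scenario labels (default two RCP-like pathways).
#' @param warming_offsets numeric matrix `[scenario, gcm]` of mean
#'   warming, degC; default `warming_base` per scenario plus an evenly
#'   spaced per-GCM spread of +/- 0.75 degC.
#' @param warming_base per-scenario central warming, degC.
#' @param precip_regime_split fraction of columns assigned the winter-wet
#'   regime (>= 70 percent of annual precipitation in Oct-Mar).
#' @param ag_fraction_range range of the per-cell agricultural fraction.
#' @param planted_pairs list of `c(target_county, analog_county)` id pairs
#'   to force as ground truth (see [plant_known_analog()]).
#' @param sd_day per-cell daily Gaussian noise sd on the daily mean
#'   temperature, degC.
#' @param sd_year grid-shared interannual temperature effect sd, degC.
#' @param precip_shape gamma shape of daily precipitation weights
#'   (`Inf` = deterministic climatology).
#' @param precip_sd_year lognormal sd of the grid-shared annual
#'   precipitation factor.
#' @param specialty_fraction fraction of counties with specialty crops.
#' @param suppressed_fraction fraction of counties whose crop list is
#'   disclosure-suppressed (`complete = FALSE`).
#' @return An object of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 1, grid_shape = c(6, 6), n_counties = 6,
#'                         n_years_hist = 5, n_gcms = 2)
#' @export
synthetic_config <- function(seed,
                             grid_shape = c(20L, 20L),
                             n_counties = 40L,
                             n_years_hist = 30L,
                             n_years_future = 10L,
                             n_gcms = 6L,
                             scenarios = c("rcp45-like", "rcp85-like"),
                             warming_offsets = NULL,
                             warming_base = c(2.0, 3.5),
                             precip_regime_split = 0.5,
                             ag_fraction_range = c(0.05, 0.95),
                             planted_pairs = list(),
                             sd_day = 1.5,
                             sd_year = 0.6,
                             precip_shape = 1,
                             precip_sd_year = 0.15,
                             specialty_fraction = 0.8,
                             suppressed_fraction = 0.1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    stop("grid_shape must be two positive integers")
  }
  n_cells <- prod(grid_shape)
  if (n_counties < 1L || n_counties > n_cells) {
    stop("n_counties must be between 1 and the number of grid cells")
  }
  if (n_years_hist < 3L) stop("n_years_hist must be >= 3")
  if (n_years_future < 2L) stop("n_years_future must be >= 2")
  if (n_gcms < 1L) stop("n_gcms must be >= 1")
  ns <- length(scenarios)
  if (is.null(warming_offsets)) {
    if (length(warming_base) != ns) {
      stop("warming_base must have one entry per scenario")
    }
    spread <- if (n_gcms > 1) seq(-0.75, 0.75, length.out = n_gcms) else 0
    warming_offsets <- outer(warming_base, rep(1, n_gcms)) +
      outer(rep(1, ns), spread)
  }
  warming_offsets <- matrix(as.numeric(warming_offsets), ns, n_gcms,
                            dimnames = list(scenarios, gcm_names(n_gcms)))
  if (!all(is.finite(warming_offsets))) {
    stop("warming offsets must be finite")
  }
  if (precip_regime_split < 0 || precip_regime_split > 1) {
    stop("precip_regime_split must lie in [0, 1]")
  }
  if (length(ag_fraction_range) != 2L || any(ag_fraction_range < 0) ||
      any(ag_fraction_range > 1) || diff(ag_fraction_range) < 0) {
    stop("ag_fraction_range must be an increasing pair inside [0, 1]")
  }
  for (p in planted_pairs) {
    if (length(p) != 2L || p[1] == p[2]) {
      stop("planted pairs must be distinct (target, analog) county ids")
    }
  }
  stopifnot(sd_day >= 0, sd_year >= 0, precip_shape > 0,
            precip_sd_year >= 0,
            specialty_fraction >= 0, specialty_fraction <= 1,
            suppressed_fraction >= 0, suppressed_fraction <= 1)
  structure(
    list(seed = as.integer(seed), grid_shape = grid_shape,
         n_counties = as.integer(n_counties),
         n_years_hist = as.integer(n_years_hist),
         n_years_future = as.integer(n_years_future),
         n_gcms = as.integer(n_gcms), scenarios = scenarios,
         warming_offsets = warming_offsets,
         precip_regime_split = precip_regime_split,
         ag_fraction_range = ag_fraction_range,
         planted_pairs = planted_pairs,
         sd_day = sd_day, sd_year = sd_year,
         precip_shape = precip_shape, precip_sd_year = precip_sd_year,
         specialty_fraction = specialty_fraction,
         suppressed_fraction = suppressed_fraction),
    class = "synthetic_config"
  )
}

gcm_names <- function(n) sprintf("gcm%02d", seq_len(n))

# Deterministic per-cell climate parameters (no RNG). Row 1 is "north".
cell_parameters <- function(config) {
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  cell_id <- seq_len(rows * cols)
  row <- (cell_id - 1L) %/% cols + 1L
  col <- (cell_id - 1L) %% cols + 1L
  row_frac <- if (rows > 1) (row - 1) / (rows - 1) else rep(0, length(row))
  col_frac <- if (cols > 1) (col - 1) / (cols - 1) else rep(0, length(col))
  data.frame(
    cell_id = cell_id, row = row, col = col,
    row_frac = row_frac, col_frac = col_frac,
    tbase = 12 + 14 * row_frac,        # annual-mean temperature, degC
    amp = 13 - 4 * row_frac,           # seasonal half-amplitude, degC
    drange = 8 + 4 * col_frac,         # diurnal range, degC
    precip_annual = 300 + 900 * col_frac, # mm
    winter_wet = col <= round(config$precip_regime_split * cols)
  )
}

# Monthly precipitation weights by regime; winter-wet concentrates 85% of
# the annual total in Oct-Mar, uniform is proportional to month length.
regime_month_weights <- function(winter_wet) {
  if (winter_wet) {
    w <- rep(0.15 / 6, 12)
    w[c(10:12, 1:3)] <- 0.85 / 6
    w
  } else {
    MONTH_DAYS / 365
  }
}

# Deterministic daily climatology matrices [cell, 365].
deterministic_climatology <- function(cells) {
  nc <- nrow(cells)
  days <- seq_len(365)
  seasonal <- cos(2 * pi * (days - 196) / 365) # peak at day 196 (mid July)
  tmean <- matrix(cells$tbase, nc, 365) + outer(cells$amp, seasonal)
  half_dr <- matrix(cells$drange / 2, nc, 365)
  wday <- t(vapply(cells$winter_wet, function(ww) {
    w <- regime_month_weights(ww)
    (w / MONTH_DAYS)[DAY_MONTH]
  }, numeric(365)))
  prcp <- matrix(cells$precip_annual, nc, 365) * wday
  list(tmax = tmean + half_dr, tmin = tmean - half_dr, prcp = prcp)
}

# One multi-year weather block: det climatology + year effects + day noise.
simulate_block <- function(det, config, n_years, dT = 0) {
  nc <- nrow(det$tmax)
  temp_eff <- if (config$sd_year > 0) {
    rnorm(n_years, 0, config$sd_year)
  } else rep(0, n_years)
  prcp_eff <- if (config$precip_sd_year > 0) {
    exp(rnorm(n_years, 0, config$precip_sd_year))
  } else rep(1, n_years)
  n <- nc * 365 * n_years
  shift <- rep(temp_eff + dT, each = nc * 365)
  if (config$sd_day > 0) shift <- shift + rnorm(n, 0, config$sd_day)
  tmax <- array(det$tmax, c(nc, 365, n_years)) + shift
  tmin <- array(det$tmin, c(nc, 365, n_years)) + shift
  wet <- if (is.finite(config$precip_shape)) {
    rgamma(n, shape = config$precip_shape, rate = config$precip_shape)
  } else rep(1, n)
  prcp <- array(det$prcp, c(nc, 365, n_years)) *
    rep(prcp_eff, each = nc * 365) * wet
  list(tmax = tmax, tmin = tmin, prcp = prcp,
       year_effects = list(temp = temp_eff, prcp = prcp_eff))
}

# Contiguous county partition: cells in row-major order are cut into
# n_counties near-equal runs; regions are the quadrants of county centers.
partition_counties <- function(config) {
  n_cells <- prod(config$grid_shape)
  sizes <- rep(n_cells %/% config$n_counties, config$n_counties)
  extra <- n_cells %% config$n_counties
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  county_id <- rep(seq_len(config$n_counties), times = sizes)
  cells <- cell_parameters(config)
  cen_row <- tapply(cells$row_frac, county_id, mean)
  cen_col <- tapply(cells$col_frac, county_id, mean)
  region_of <- ifelse(cen_row < 0.5,
                      ifelse(cen_col < 0.5, "NW", "NE"),
                      ifelse(cen_col < 0.5, "SW", "SE"))
  data.frame(cell_id = cells$cell_id, county_id = county_id,
             region = region_of[county_id])
}

#' Generate a complete synthetic dataset
#'
#' Draws, from `config$seed` alone, the historical gridded daily weather,
#' the pseudo-GCM future ensemble (historical climatology + per-GCM
#' warming offset + per-GCM noise), the land-use field, the county
#' partition, and the crop census; then applies any planted target-analog
#' pairs. Identical configs give identical datasets.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `analog_dataset`: a list with `config`,
#'   `cells` (per-cell parameters), `det` (deterministic climatology),
#'   `historical` / `future` daily arrays `[cell, 365, year]` (future is
#'   nested `[[scenario]][[gcm]]`), `landuse`, `county_map`, `crop_census`
#'   and `truth` (planted pairs).
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cells <- cell_parameters(config)
  det <- deterministic_climatology(cells)
  county_map <- partition_counties(config)

  landuse <- data.frame(
    cell_id = cells$cell_id,
    ag_fraction = runif(nrow(cells), config$ag_fraction_range[1],
                        config$ag_fraction_range[2])
  )

  hist_block <- simulate_block(det, config, config$n_years_hist)
  historical <- list(tmax = hist_block$tmax, tmin = hist_block$tmin,
                     prcp = hist_block$prcp,
                     years = 1990L + seq_len(config$n_years_hist))

  future <- list(); future_effects <- list()
  for (s in config$scenarios) {
    future[[s]] <- list(); future_effects[[s]] <- list()
    for (g in gcm_names(config$n_gcms)) {
      blk <- simulate_block(det, config, config$n_years_future,
                            dT = config$warming_offsets[s, g])
      future[[s]][[g]] <- list(tmax = blk$tmax, tmin = blk$tmin,
                               prcp = blk$prcp,
                               years = 2040L + seq_len(config$n_years_future))
      future_effects[[s]][[g]] <- blk$year_effects
    }
  }

  crop_census <- generate_crop_census(config, county_map)

  dataset <- structure(
    list(config = config, cells = cells, det = det,
         historical = historical, future = future,
         future_year_effects = future_effects,
         landuse = landuse, county_map = county_map,
         crop_census = crop_census, truth = list()),
    class = "analog_dataset"
  )
  for (p in config$planted_pairs) {
    dataset <- plant_known_analog(dataset, p[1], p[2])
  }
  dataset
}

#' @export
print.analog_dataset <- function(x, ...) {
  cat(sprintf(
    "<analog_dataset> %d cells, %d counties, %d hist years, %d GCMs x %d scenarios, %d planted pair(s)\n",
    nrow(x$cells), x$config$n_counties, x$config$n_years_hist,
    x$config$n_gcms, length(x$config$scenarios), length(x$truth)))
  invisible(x)
}

county_cells <- function(dataset, county_id) {
  idx <- dataset$county_map$cell_id[dataset$county_map$county_id == county_id]
  if (length(idx) == 0L) stop(sprintf("unknown county id: %s", county_id))
  idx
}

#' Plant a known target-analog ground truth
#'
#' Replaces the target county's future daily series (every GCM and
#' scenario) with the analog county's historical deterministic climatology
#' (ag-cell mean) plus the dataset's stored year-level effects and freshly
#' drawn day-level noise with the dataset's own noise parameters, so the
#' target's future normals match the analog's historical normals in
#' expectation. Day-level noise must be included: the derived indices are
#' nonlinear in the daily values (clipping, thresholds, monthly maxima),
#' so a noise-free series would have systematically shifted normals. The
#' extra draws come from a private RNG stream derived from the dataset
#' seed and the pair ids; the global RNG state is restored on exit. By default also copies the analog's crop list onto the
#' target (identical specialty sets, match fraction 1) and raises both
#' counties' specialty acreage above the existing maximum so the planted
#' target survives 99-percent-coverage target selection.
#'
#' @param dataset an `analog_dataset`.
#' @param target,analog distinct county ids present in the dataset.
#' @param copy_crops copy crop lists and boost acreage (default `TRUE`).
#' @return The modified dataset; the pair is appended to `dataset$truth`.
#' @export
plant_known_analog <- function(dataset, target, analog, copy_crops = TRUE) {
  stopifnot(inherits(dataset, "analog_dataset"))
  if (target == analog) stop("target and analog must be distinct counties")
  t_cells <- county_cells(dataset, target)
  a_cells <- county_cells(dataset, analog)

  ag <- dataset$landuse$ag_fraction[a_cells] >= 0.125
  src <- if (any(ag)) a_cells[ag] else a_cells
  clim_tmax <- colMeans(dataset$det$tmax[src, , drop = FALSE])
  clim_tmin <- colMeans(dataset$det$tmin[src, , drop = FALSE])
  clim_prcp <- colMeans(dataset$det$prcp[src, , drop = FALSE])

  cfg <- dataset$config
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed((cfg$seed + 7919 * as.numeric(target) +
              104729 * as.numeric(analog)) %% .Machine$integer.max)

  nt <- length(t_cells)
  for (s in names(dataset$future)) {
    for (g in names(dataset$future[[s]])) {
      eff <- dataset$future_year_effects[[s]][[g]]
      ny <- length(eff$temp)
      n <- nt * 365 * ny
      base_tx <- array(rep(clim_tmax, each = nt), c(nt, 365, ny))
      base_tn <- array(rep(clim_tmin, each = nt), c(nt, 365, ny))
      base_pr <- array(rep(clim_prcp, each = nt), c(nt, 365, ny))
      shift <- rep(eff$temp, each = nt * 365)
      if (cfg$sd_day > 0) shift <- shift + rnorm(n, 0, cfg$sd_day)
      pfac <- rep(eff$prcp, each = nt * 365)
      if (is.finite(cfg$precip_shape)) {
        pfac <- pfac * rgamma(n, shape = cfg$precip_shape,
                              rate = cfg$precip_shape)
      }
      dataset$future[[s]][[g]]$tmax[t_cells, , ] <- base_tx + shift
      dataset$future[[s]][[g]]$tmin[t_cells, , ] <- base_tn + shift
      dataset$future[[s]][[g]]$prcp[t_cells, , ] <- base_pr * pfac
    }
  }

  if (copy_crops) {
    dataset$crop_census <- plant_crop_truth(dataset$crop_census,
                                            target, analog)
  }
  dataset$truth <- c(dataset$truth,
                     list(list(target = target, analog = analog)))
  dataset
}

SPECIALTY_GROUPS <- c("vegetable", "fruit", "tree nut", "berry")

plant_crop_truth <- function(census, target, analog) {
  a_rows <- census[census$county_id == analog, , drop = FALSE]
  sp <- a_rows$group %in% SPECIALTY_GROUPS
  if (!any(sp)) {
    a_rows <- rbind(
      a_rows[!sp, , drop = FALSE],
      data.frame(county_id = analog,
                 crop = c("peaches", "blueberries", "pecans"),
                 group = c("fruit", "berry", "tree nut"),
                 acres = c(800, 500, 400), complete = TRUE)
    )
    sp <- a_rows$group %in% SPECIALTY_GROUPS
  }
  t_rows <- a_rows
  t_rows$county_id <- target
  census <- census[!(census$county_id %in% c(target, analog)), , drop = FALSE]
  # boost both counties above the current specialty maximum so that the
  # planted target is always selected as a top-coverage target county
  sp_tot <- tapply(census$acres[census$group %in% SPECIALTY_GROUPS],
                   census$county_id[census$group %in% SPECIALTY_GROUPS], sum)
  cap <- if (length(sp_tot)) max(sp_tot) else 1000
  for (df_name in c("a_rows", "t_rows")) {
    df <- get(df_name)
    tot <- sum(df$acres[df$group %in% SPECIALTY_GROUPS])
    df$acres[df$group %in% SPECIALTY_GROUPS] <-
      df$acres[df$group %in% SPECIALTY_GROUPS] * 1.05 * cap / tot
    df$complete <- TRUE
    assign(df_name, df)
  }
  out <- rbind(census, a_rows, t_rows)
  out[order(out$county_id, out$crop), , drop = FALSE]
}
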