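# Vectorized metric engine over weather arrays [cell, day(365), year].
# The per-series operations in agro-metrics.R define the semantics; this
# file computes the same quantities for all cells/years at once so a
# full-grid multi-GCM run stays within desk-scale runtime.

sum_over_days <- function(a) {
  # a: [cell, day, year] -> [cell, year]
  d <- dim(a)
  out <- matrix(0, d[1], d[3])
  for (y in seq_len(d[3])) {
    out[, y] <- rowSums(a[, , y, drop = FALSE], dims = 1)
  }
  out
}

bulk_gdd <- function(tmax, tmin, thresholds) {
  hi <- pmin(pmax(tmax, thresholds$gdd_base), thresholds$gdd_upper)
  lo <- pmin(pmax(tmin, thresholds$gdd_base), thresholds$gdd_upper)
  # NB: array first in pmax so the dim attribute survives
  sum_over_days(pmax((hi + lo) / 2 - thresholds$gdd_base, 0))
}

bulk_season_length <- function(tmin, thresholds) {
  d <- dim(tmin)
  out <- matrix(0L, d[1], d[3])
  for (y in seq_len(d[3])) {
    ok <- tmin[, , y] > thresholds$frost_threshold # [cell, day]
    out[, y] <- apply(ok, 1, longest_run)
  }
  out
}

bulk_hdh <- function(tmax, tmin, thresholds) {
  jas <- SEASON_DAYS$jas
  m <- (tmax[, jas, , drop = FALSE] + tmin[, jas, , drop = FALSE]) / 2
  a <- (tmax[, jas, , drop = FALSE] - tmin[, jas, , drop = FALSE]) / 2
  acc <- array(0, dim(m))
  for (s in HOUR_SINE) {
    acc <- acc + pmax(m + a * s - thresholds$heat_threshold, 0)
  }
  sum_over_days(acc)
}

bulk_chill <- function(tmax, tmin, thresholds) {
  # year y needs Oct-Dec of year y-1; first year is NA
  d <- dim(tmax)
  out <- matrix(NA_real_, d[1], d[3])
  for (y in seq_len(d[3])[-1]) {
    tx <- cbind(tmax[, CHILL_PRIOR_DAYS, y - 1], tmax[, CHILL_CURRENT_DAYS, y])
    tn <- cbind(tmin[, CHILL_PRIOR_DAYS, y - 1], tmin[, CHILL_CURRENT_DAYS, y])
    m <- (tx + tn) / 2
    a <- (tx - tn) / 2
    cnt <- matrix(0, nrow(m), ncol(m))
    for (s in HOUR_SINE) {
      t <- m + a * s
      cnt <- cnt + (t >= thresholds$chill_low & t <= thresholds$chill_high)
    }
    out[, y] <- rowSums(cnt)
  }
  out
}

MONTH_IND <- local({
  m <- matrix(0, 365, 12)
  m[cbind(seq_len(365), DAY_MONTH)] <- 1
  m
})

bulk_precip_range <- function(prcp) {
  d <- dim(prcp)
  out <- matrix(0, d[1], d[3])
  for (y in seq_len(d[3])) {
    mon <- prcp[, , y] %*% MONTH_IND # [cell, 12]
    out[, y] <- apply(mon, 1, max) - apply(mon, 1, min)
  }
  out
}

SEASON_MEAN_IND <- local({
  m <- matrix(0, 365, 4)
  for (j in seq_along(SEASON_DAYS)) {
    m[SEASON_DAYS[[j]], j] <- 1 / length(SEASON_DAYS[[j]])
  }
  m
})
SEASON_SUM_IND <- local({
  m <- matrix(0, 365, 4)
  for (j in seq_along(SEASON_DAYS)) m[SEASON_DAYS[[j]], j] <- 1
  m
})

#' Bulk annual climate vectors for a weather array
#'
#' Computes the per-cell, per-year climate vectors for every cell of a
#' weather block at once. `weather` is a list with `tmax`, `tmin`, `prcp`
#' arrays of dimension `[cell, 365, year]` (as stored in a synthetic
#' dataset). For `mode = "context"` the first year is `NA` (incomplete
#' chill season); callers drop it.
#'
#' @param weather list of `tmax`, `tmin`, `prcp` arrays `[cell, 365, year]`.
#' @param mode `"context"` (5 variables) or `"generic"` (8 variables).
#' @param thresholds a [metric_thresholds()] object.
#' @return numeric array `[cell, year, variable]` with named variables.
#' @export
climate_vectors <- function(weather, mode = c("context", "generic"),
                            thresholds = metric_thresholds()) {
  mode <- match.arg(mode)
  tx <- weather$tmax; tn <- weather$tmin; pr <- weather$prcp
  stopifnot(length(dim(tx)) == 3L, dim(tx)[2] == 365L)
  d <- dim(tx)
  vars <- variable_names(mode)
  out <- array(NA_real_, c(d[1], d[3], length(vars)),
               dimnames = list(NULL, NULL, vars))
  if (mode == "context") {
    out[, , "gdd"] <- bulk_gdd(tx, tn, thresholds)
    out[, , "season_length"] <- bulk_season_length(tn, thresholds)
    out[, , "hdh"] <- bulk_hdh(tx, tn, thresholds)
    out[, , "chill"] <- bulk_chill(tx, tn, thresholds)
    out[, , "precip_range"] <- bulk_precip_range(pr)
  } else {
    for (y in seq_len(d[3])) {
      tm <- (tx[, , y] + tn[, , y]) / 2
      out[, y, 1:4] <- tm %*% SEASON_MEAN_IND
      out[, y, 5:8] <- pr[, , y] %*% SEASON_SUM_IND
    }
  }
  out
}
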