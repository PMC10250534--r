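#' Bilinear regridding of a fine grid onto a coarser one
#'
#' Downsamples a fine-resolution field to a coarse grid whose resolution is
#' an integer refinement `factor` of the fine one, by bilinear
#' interpolation at the coarse-cell centers (cell-center registration).
#' Constant fields map to the same constant and a linear ramp stays on the
#' ramp.
#'
#' @param field numeric matrix on the fine grid; both dimensions must be
#'   multiples of `factor`.
#' @param factor integer refinement factor (fine cells per coarse cell and
#'   dimension).
#' @return numeric matrix of dimension `dim(field) / factor`.
#' @export
regrid_linear <- function(field, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  d <- dim(field)
  if (is.null(d) || any(d %% factor != 0L)) {
    stop("fine grid must be an integer refinement of the coarse grid")
  }
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  # coarse-cell centers in fine cell-index coordinates
  ctr <- function(n) (seq_len(n) - 0.5) * factor + 0.5
  interp1 <- function(pos, nmax) {
    i0 <- pmin(pmax(floor(pos), 1L), nmax - 1L)
    list(lo = i0, w = pos - i0)
  }
  rx <- interp1(ctr(nr), d[1]); cx <- interp1(ctr(nc), d[2])
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    c0 <- cx$lo[j]; wc <- cx$w[j]
    col_lo <- field[, c0] * (1 - wc) + field[, c0 + 1L] * wc
    out[, j] <- col_lo[rx$lo] * (1 - rx$w) + col_lo[rx$lo + 1L] * rx$w
  }
  out
}

#' Agricultural cell mask
#'
#' Flags a cell as agricultural when its agricultural land fraction is at
#' least `threshold` (default 1/8, inclusive).
#'
#' @param landuse numeric vector of agricultural fractions in `[0, 1]`, or
#'   a data.frame with `cell_id` and `ag_fraction` columns.
#' @param threshold inclusive agricultural-fraction cutoff.
#' @return logical vector (named by `cell_id` for data.frame input).
#' @examples
#' build_ag_mask(c(0.125, 0.124, 0)) # TRUE FALSE FALSE
#' @export
build_ag_mask <- function(landuse, threshold = 1 / 8) {
  if (is.data.frame(landuse)) {
    frac <- setNames(landuse$ag_fraction, landuse$cell_id)
  } else {
    frac <- landuse
  }
  if (any(frac < 0 | frac > 1)) stop("ag fractions must lie in [0, 1]")
  frac >= threshold
}

#' County-level climate vector for one year
#'
#' Unweighted mean of each variable across the county's agricultural
#' cells. A county with no agricultural cell is excluded from the analog
#' pool; this function signals that case as an error (bulk aggregation
#' logs and drops such counties instead).
#'
#' @param cell_vectors numeric matrix `[cell, variable]` of per-cell values
#'   for one year, rows indexed by `cell_id`.
#' @param county_map data.frame with `cell_id`, `county_id`.
#' @param county_id the county to aggregate.
#' @param mask logical agricultural mask indexed like the grid cells.
#' @return named numeric vector of county means.
#' @export
county_yearly_vector <- function(cell_vectors, county_map, county_id,
                                 mask = rep(TRUE, nrow(cell_vectors))) {
  idx <- county_map$cell_id[county_map$county_id == county_id]
  idx <- idx[mask[idx]]
  if (length(idx) == 0L) {
    stop(sprintf("county %s has no agricultural cells; excluded", county_id))
  }
  colMeans(cell_vectors[idx, , drop = FALSE])
}

# Bulk form: cell_values [cell, year, k] -> named list of [year, k]
# matrices per county. Counties without agricultural cells are dropped and
# recorded in the "excluded" attribute.
aggregate_counties <- function(cell_values, county_map, mask) {
  counties <- sort(unique(county_map$county_id))
  out <- list(); excluded <- integer(0)
  for (cid in counties) {
    idx <- county_map$cell_id[county_map$county_id == cid]
    idx <- idx[mask[idx]]
    if (length(idx) == 0L) { excluded <- c(excluded, cid); next }
    block <- cell_values[idx, , , drop = FALSE]
    out[[as.character(cid)]] <- colMeans(block, dims = 1) # [year, k]
  }
  if (length(excluded)) {
    message(sprintf("excluded %d county(ies) with no agricultural cells: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  attr(out, "excluded") <- excluded
  out
}

#' County climate profile: normal and interannual variability
#'
#' From a year-by-variable matrix of annual county values, computes the
#' climate normal (per-variable mean), detrends each variable linearly
#' against the year label (OLS), and forms the interannual climatic
#' variability (ICV) covariance from the residuals. If the covariance is
#' ill-conditioned (condition number > 1e10, e.g. a zero-variance
#' variable), a ridge `eps * I` is added with
#' `eps = 1e-8 * mean(diag(cov))` (absolute fallback `1e-8` when the
#' covariance is identically zero), with a warning.
#'
#' @param yearly numeric matrix `[year, variable]`; >= 3 rows. Row names,
#'   if present, are used as year labels for detrending (otherwise the row
#'   index is used), so profiles are invariant to permuting years together
#'   with their labels.
#' @param county_id optional id stored in the profile.
#' @return An object of class `county_profile`: list with `county_id`,
#'   `variable_names`, `normal`, `icv_series`, `icv_cov`, `n_years`.
#' @export
build_profile <- function(yearly, county_id = NA) {
  yearly <- as.matrix(yearly)
  if (nrow(yearly) < 3L) stop("at least 3 years required to build a profile")
  if (anyNA(yearly)) stop("yearly values contain missing entries")
  years <- suppressWarnings(as.numeric(rownames(yearly)))
  if (is.null(rownames(yearly)) || anyNA(years)) years <- seq_len(nrow(yearly))
  normal <- colMeans(yearly)
  resid <- apply(yearly, 2, function(v) {
    f <- lm.fit(cbind(1, years), v)
    f$residuals
  })
  icv_cov <- cov(resid)
  k <- ncol(icv_cov)
  ev <- eigen(icv_cov, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  if (!is.finite(cond) || cond > 1e10) {
    eps <- 1e-8 * mean(diag(icv_cov))
    if (eps <= 0) eps <- 1e-8
    icv_cov <- icv_cov + diag(eps, k)
    warning(sprintf(
      "degenerate ICV covariance for county %s; ridge %.3g added",
      county_id, eps))
  }
  structure(
    list(county_id = county_id, variable_names = colnames(yearly),
         normal = normal, icv_series = yearly, icv_cov = icv_cov,
         n_years = nrow(yearly)),
    class = "county_profile"
  )
}

#' @export
print.county_profile <- function(x, ...) {
  cat(sprintf("<county_profile> county %s, %d years, %d variable(s)\n",
              x$county_id, x$n_years, length(x$normal)))
  invisible(x)
}
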