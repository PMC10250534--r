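#' Interannual-variability-scaled Mahalanobis distance
#'
#' Distance between a target county's projected future climate normal and a
#' candidate county's historical normal, with variables scaled by the
#' candidate's historical interannual-variability (ICV) covariance:
#' `sqrt(d' C^-1 d)` with `d = target - candidate`, solved through a
#' Cholesky factorization (never an explicit inverse). Reduces to the
#' Euclidean distance for an identity covariance.
#'
#' @param target_future_normal,candidate_hist_normal numeric vectors of
#'   equal length `k`.
#' @param candidate_icv_cov symmetric positive-definite `k x k` matrix
#'   (post-ridge; see [build_profile()]).
#' @return non-negative scalar distance (dimensionless).
#' @examples
#' mahalanobis_distance(c(3, 4), c(0, 0), diag(2)) # 5
#' @export
mahalanobis_distance <- function(target_future_normal,
                                 candidate_hist_normal,
                                 candidate_icv_cov) {
  k <- length(target_future_normal)
  if (length(candidate_hist_normal) != k ||
      !all(dim(candidate_icv_cov) == k)) {
    stop("dimension mismatch between vectors and covariance")
  }
  d <- target_future_normal - candidate_hist_normal
  if (!all(is.finite(d)) || !all(is.finite(candidate_icv_cov))) {
    stop("non-finite inputs")
  }
  R <- chol(candidate_icv_cov)
  z <- backsolve(R, d, transpose = TRUE)
  sqrt(sum(z^2))
}

# Many targets against one candidate: X is [target, k].
mahalanobis_block <- function(X, candidate_hist_normal, candidate_icv_cov) {
  D <- sweep(X, 2, candidate_hist_normal)
  R <- chol(candidate_icv_cov)
  Z <- backsolve(R, t(D), transpose = TRUE)
  sqrt(colSums(Z^2))
}

#' Sigma dissimilarity of a Mahalanobis distance
#'
#' Re-expresses a Mahalanobis distance in `dof` dimensions as the
#' equivalent one-dimensional sigma level: the chi-distribution
#' (`dof` degrees of freedom) percentile of the distance is mapped back
#' through the quantile of the chi distribution with 1 degree of freedom.
#' 2-sigma corresponds to the 95.45th percentile and 4-sigma to the
#' 99.994th. Survival functions are used in log space so extreme
#' percentiles do not underflow; values are capped at `cap` (default 10)
#' with a `saturated` attribute, which preserves ordering for the 2/4
#' sigma classification thresholds.
#'
#' @param distance non-negative Mahalanobis distance(s).
#' @param dof degrees of freedom (number of climate variables).
#' @param cap saturation value for the sigma scale.
#' @return sigma value(s), with logical attribute `saturated`.
#' @examples
#' sigma_dissimilarity(sqrt(qchisq(0.95, 5)), 5) # 1.95996...
#' @export
sigma_dissimilarity <- function(distance, dof, cap = 10) {
  if (any(distance < 0)) stop("distance must be non-negative")
  if (any(dof < 1)) stop("dof must be >= 1")
  if (length(dof) == 1L && dof == 1) {
    # chi(1) percentile mapped through chi(1) quantile: exact identity
    sigma <- distance
  } else {
    log_sf <- pchisq(distance^2, df = dof, lower.tail = FALSE, log.p = TRUE)
    sigma <- sqrt(qchisq(log_sf, df = 1, lower.tail = FALSE, log.p = TRUE))
  }
  sat <- sigma > cap
  sigma <- pmin(sigma, cap)
  attr(sigma, "saturated") <- sat
  sigma
}

#' Classify sigma dissimilarities
#'
#' Inclusive thresholds: `sigma <= accept` (default 2) is an acceptable
#' analog, `sigma >= novel` (default 4) is a novel-range climate,
#' everything between is intermediate.
#'
#' @param sigma numeric sigma dissimilarities.
#' @param accept,novel classification thresholds (`0 < accept < novel`).
#' @return factor with levels `acceptable`, `intermediate`, `novel-range`.
#' @export
classify_analogs <- function(sigma, accept = 2, novel = 4) {
  stopifnot(accept > 0, accept < novel)
  out <- ifelse(sigma <= accept, "acceptable",
                ifelse(sigma >= novel, "novel-range", "intermediate"))
  factor(out, levels = c("acceptable", "intermediate", "novel-range"))
}

#' Multi-GCM consensus analog sets
#'
#' A candidate is retained in a target's consensus set for a scenario when
#' it is an acceptable analog in at least `m` GCMs. A target is flagged
#' `no_analog` when its consensus set is empty, and `novel` when
#' additionally every candidate is at or beyond the novel threshold in
#' every GCM.
#'
#' @param records data.frame of distance records with columns `target_id`,
#'   `candidate_id`, `scenario`, `gcm`, `sigma`, `category` (from
#'   [compute_distances()]).
#' @param m consensus threshold; `1 <= m <=` number of GCMs. Default
#'   [consensus_threshold()] of the ensemble size.
#' @param novel novel-climate sigma threshold used for the `novel` flag.
#' @return list of class `consensus_set` with `members` (data.frame
#'   `target_id`, `scenario`, `analog_id`, `n_gcms_supporting`), `targets`
#'   (data.frame `target_id`, `scenario`, `n_analogs`, `no_analog`,
#'   `novel`) and `m`.
#' @export
consensus_analogs <- function(records, m = NULL, novel = 4) {
  n_gcms <- length(unique(records$gcm))
  if (n_gcms < 1L) stop("at least one GCM required")
  if (is.null(m)) m <- consensus_threshold(n_gcms)
  if (m < 1 || m > n_gcms) stop("consensus m must lie in [1, n_gcms]")
  acc <- records[records$category == "acceptable", , drop = FALSE]
  counts <- if (nrow(acc)) {
    agg <- aggregate(list(n_gcms_supporting = acc$gcm),
                     by = list(target_id = acc$target_id,
                               scenario = acc$scenario,
                               analog_id = acc$candidate_id),
                     FUN = function(g) length(unique(g)))
    agg[agg$n_gcms_supporting >= m, , drop = FALSE]
  } else {
    data.frame(target_id = integer(0), scenario = character(0),
               analog_id = integer(0), n_gcms_supporting = integer(0))
  }
  counts <- counts[order(counts$target_id, counts$scenario,
                         counts$analog_id), , drop = FALSE]
  rownames(counts) <- NULL

  # per-target flags over all candidates/GCMs
  tg <- unique(records[, c("target_id", "scenario")])
  tg <- tg[order(tg$target_id, tg$scenario), , drop = FALSE]
  tg$n_analogs <- mapply(function(t, s) {
    sum(counts$target_id == t & counts$scenario == s)
  }, tg$target_id, tg$scenario)
  tg$no_analog <- tg$n_analogs == 0L
  min_sigma <- aggregate(list(min_sigma = records$sigma),
                         by = list(target_id = records$target_id,
                                   scenario = records$scenario),
                         FUN = min)
  tg <- merge(tg, min_sigma, by = c("target_id", "scenario"), sort = FALSE)
  tg$novel <- tg$no_analog & tg$min_sigma >= novel
  tg$min_sigma <- NULL
  rownames(tg) <- NULL
  structure(list(members = counts, targets = tg, m = m),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> m = %d; %d membership row(s), %d target/scenario combination(s)\n",
              x$m, nrow(x$members), nrow(x$targets)))
  invisible(x)
}

# Analog ids of one target/scenario from a consensus_set
consensus_ids <- function(consensus, target_id, scenario) {
  m <- consensus$members
  m$analog_id[m$target_id == target_id & m$scenario == scenario]
}

#' Consensus threshold for an ensemble of a given size
#'
#' `floor(0.25 * n_gcms) + 1`: the smallest count strictly above a quarter
#' of the ensemble. Gives the conventional 5-of-19 for a 19-member
#' ensemble and scales the same "> 25 percent of the GCMs" rule to smaller
#' ensembles.
#'
#' @param n_gcms ensemble size.
#' @return integer threshold.
#' @export
consensus_threshold <- function(n_gcms) {
  if (n_gcms < 1) stop("n_gcms must be >= 1")
  min(as.integer(floor(0.25 * n_gcms) + 1L), as.integer(n_gcms))
}

#' Overlap (Jaccard) of two analog sets
#'
#' `|A intersect B| / |A union B|`; 0 for completely different sets, 1 for
#' identical sets. Two empty sets count as agreement (1.0) and are flagged
#' through the `both_empty` attribute so reporting can exclude them.
#'
#' @param set_a,set_b vectors of analog county ids.
#' @return fraction in `[0, 1]` with attribute `both_empty`.
#' @examples
#' analogset_overlap(c("a", "b", "c"), c("b", "c", "d")) # 0.5
#' @export
analogset_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L) {
    return(structure(1.0, both_empty = TRUE))
  }
  structure(length(intersect(a, b)) / length(union(a, b)),
            both_empty = FALSE)
}

#' Closed-form comparison count of a full analog run
#'
#' Number of distance records produced by a run over `n_targets` target
#' counties, `n_gcms` GCMs, `n_scenarios` scenarios and `n_candidates`
#' candidate counties (every pairing is computed, including self-pairs).
#'
#' @param n_targets,n_gcms,n_scenarios,n_candidates pool sizes.
#' @return the product, as a double.
#' @export
comparison_count <- function(n_targets, n_gcms, n_scenarios, n_candidates) {
  as.numeric(n_targets) * n_gcms * n_scenarios * n_candidates
}

#' Distance records for all target/candidate/scenario/GCM combinations
#'
#' Computes, for one variable mode, the ICV-scaled Mahalanobis distance
#' between every target's per-GCM future normal and every candidate's
#' historical normal (scaled by the candidate's historical ICV
#' covariance), maps it to sigma dissimilarity with `dof = k` (the number
#' of variables), and classifies each record.
#'
#' @param profiles named list of historical [build_profile()] objects
#'   (the candidate pool), names = county ids.
#' @param future_normals nested list `[[scenario]][[gcm]]` of numeric
#'   matrices `[county, k]` with county ids as row names (targets).
#' @param target_ids county ids to use as targets (default: all rows of
#'   the future normals).
#' @param accept,novel classification thresholds.
#' @return data.frame with columns `target_id`, `candidate_id`,
#'   `scenario`, `gcm`, `mahalanobis`, `dof`, `sigma`, `category`.
#' @export
compute_distances <- function(profiles, future_normals, target_ids = NULL,
                              accept = 2, novel = 4) {
  cand_ids <- names(profiles)
  k <- length(profiles[[1]]$normal)
  out <- list(); n <- 0L
  for (s in names(future_normals)) {
    for (g in names(future_normals[[s]])) {
      fn <- future_normals[[s]][[g]]
      tids <- if (is.null(target_ids)) rownames(fn) else
        as.character(target_ids)
      X <- fn[tids, , drop = FALSE]
      for (cid in cand_ids) {
        p <- profiles[[cid]]
        dist <- mahalanobis_block(X, p$normal, p$icv_cov)
        sg <- sigma_dissimilarity(dist, dof = k)
        n <- n + 1L
        out[[n]] <- data.frame(
          target_id = tids, candidate_id = cid, scenario = s, gcm = g,
          mahalanobis = dist, dof = k, sigma = as.numeric(sg),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$category <- classify_analogs(res$sigma, accept, novel)
  res
}
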