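#' Code counties as specialty / non-specialty from a crop census
#'
#' A county is a specialty crop county when its total acreage in the
#' specialty groups (vegetable, fruit, tree nut, berry) is positive.
#' Disclosure-suppressed counties keep their acreage totals but carry
#' `complete = FALSE`.
#'
#' @param census data.frame with `county_id`, `crop`, `group`, `acres` and
#'   optional `complete` columns; `group` must be one of the specialty
#'   groups or `"non-specialty"`.
#' @return named list of `crop_mix` objects (one per county), each with
#'   `county_id`, `crops`, `specialty_crops`, `specialty_acres`,
#'   `complete`.
#' @export
code_specialty <- function(census) {
  known <- c(SPECIALTY_GROUPS, "non-specialty")
  bad <- setdiff(unique(census$group), known)
  if (length(bad)) {
    stop(sprintf("unknown crop group label(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(census$complete)) census$complete <- TRUE
  out <- lapply(split(census, census$county_id), function(df) {
    sp <- df$group %in% SPECIALTY_GROUPS
    structure(
      list(county_id = df$county_id[1],
           crops = unique(df$crop),
           specialty_crops = unique(df$crop[sp]),
           specialty_acres = sum(df$acres[sp]),
           specialty = sum(df$acres[sp]) > 0,
           complete = all(df$complete)),
      class = "crop_mix")
  })
  out
}

#' @export
print.crop_mix <- function(x, ...) {
  cat(sprintf("<crop_mix> county %s: %d crop(s), %d specialty, %.0f specialty acres%s\n",
              x$county_id, length(x$crops), length(x$specialty_crops),
              x$specialty_acres, if (x$complete) "" else " (suppressed)"))
  invisible(x)
}

#' Select target counties covering a share of specialty acreage
#'
#' Sorts specialty counties by specialty acreage (descending, ties broken
#' by county id for determinism) and keeps the shortest prefix whose
#' cumulative share of total specialty acreage reaches `coverage`
#' (default 99 percent; the county that crosses the threshold is
#' included).
#'
#' @param crop_mixes list of `crop_mix` objects from [code_specialty()].
#' @param coverage cumulative acreage share to reach, in `(0, 1]`.
#' @return data.frame with `county_id`, `specialty_acres`, `share`,
#'   `cum_share` for the selected targets, in selection order.
#' @export
select_targets <- function(crop_mixes, coverage = 0.99) {
  stopifnot(coverage > 0, coverage <= 1)
  sp <- Filter(function(m) m$specialty, crop_mixes)
  if (length(sp) == 0L) stop("no specialty counties in census")
  df <- data.frame(
    county_id = vapply(sp, function(m) m$county_id, numeric(1)),
    specialty_acres = vapply(sp, function(m) m$specialty_acres, numeric(1))
  )
  total <- sum(df$specialty_acres)
  if (total <= 0) stop("zero total specialty acreage")
  df <- df[order(-df$specialty_acres, df$county_id), , drop = FALSE]
  df$share <- df$specialty_acres / total
  df$cum_share <- cumsum(df$share)
  keep <- seq_len(match(TRUE, df$cum_share >= coverage - 1e-12))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crop-mix match fraction of a target-analog pair
#'
#' Jaccard similarity of the two specialty crop sets:
#' `|S_t intersect S_a| / |S_t union S_a|`; 0 when the union is empty.
#' Pairs involving an incomplete (suppressed) crop list cannot be scored
#' and return `NA`, so callers exclude them from match statistics.
#'
#' @param target,analog `crop_mix` objects.
#' @return fraction in `[0, 1]`, or `NA` for an unscorable pair.
#' @examples
#' # {peach, blueberry, pecan} vs {peach, blueberry, leafy greens, pecan}
#' # -> 3/4
#' @export
crop_match_fraction <- function(target, analog) {
  if (!isTRUE(target$complete) || !isTRUE(analog$complete)) {
    return(NA_real_)
  }
  a <- unique(target$specialty_crops); b <- unique(analog$specialty_crops)
  u <- union(a, b)
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

#' Best crop match among a target's consensus analogs
#'
#' Scores every acceptable consensus analog of a target (self-pairs
#' excluded) and reports the maximum match fraction, the best analog, and
#' the target's three-way analog-existence category: at least one analog
#' in another specialty crop county (`has-specialty-analog`), analogs only
#' in non-specialty counties (`only-nonspecialty-analog`), or no analogs
#' at all (`no-analog`). Pairs with incomplete crop lists stay in the
#' analog set but are excluded from the match statistics.
#'
#' @param target_id target county id.
#' @param consensus a `consensus_set` from [consensus_analogs()].
#' @param crop_mixes list from [code_specialty()].
#' @param scenario scenario label to evaluate.
#' @return list of class `match_result` with `target_id`, `scenario`,
#'   `analog_ids`, `match_fractions`, `max_match_fraction` (NA when no
#'   scorable pair), `best_analog_id`, `category`.
#' @export
max_match <- function(target_id, consensus, crop_mixes, scenario) {
  ids <- consensus_ids(consensus, target_id, scenario)
  others <- setdiff(as.character(ids), as.character(target_id))
  tmix <- crop_mixes[[as.character(target_id)]]
  category <- if (length(others) == 0L) {
    "no-analog"
  } else {
    sp <- vapply(others, function(id) {
      m <- crop_mixes[[id]]
      !is.null(m) && isTRUE(m$specialty)
    }, logical(1))
    if (any(sp)) "has-specialty-analog" else "only-nonspecialty-analog"
  }
  fr <- vapply(others, function(id) {
    m <- crop_mixes[[id]]
    if (is.null(m)) NA_real_ else crop_match_fraction(tmix, m)
  }, numeric(1))
  scorable <- !is.na(fr)
  best <- if (any(scorable)) others[which.max(ifelse(scorable, fr, -Inf))]
          else NA_character_
  structure(
    list(target_id = target_id, scenario = scenario,
         analog_ids = others,
         match_fractions = fr,
         max_match_fraction = if (any(scorable)) max(fr[scorable]) else
           NA_real_,
         best_analog_id = best,
         category = category),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> target %s [%s]: %s, max match %.2f (best: %s)\n",
              x$target_id, x$scenario, x$category,
              ifelse(is.na(x$max_match_fraction), NaN,
                     x$max_match_fraction),
              x$best_analog_id))
  invisible(x)
}
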