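# Built-in crop catalog. Each specialty crop has a preferred latitude
# fraction (0 = north) so that climatically similar counties tend to share
# crops, as in the real census.
crop_catalog <- function() {
  sp <- data.frame(
    crop = c("sweet corn", "tomatoes", "lettuce", "onions", "carrots",
             "bell peppers", "melons", "squash", "spinach",
             "apples", "peaches", "cherries", "pears", "oranges",
             "grapes", "apricots",
             "almonds", "pecans", "walnuts", "hazelnuts", "pistachios",
             "blueberries", "strawberries", "raspberries", "cranberries"),
    group = c(rep("vegetable", 9), rep("fruit", 7), rep("tree nut", 5),
              rep("berry", 4))
  )
  sp$pref <- (seq_len(nrow(sp)) %% 10) / 9 # spread preferences over [0,1]
  ns <- data.frame(
    crop = c("wheat", "corn", "soybeans", "hay", "barley", "oats",
             "cotton", "sorghum"),
    group = "non-specialty", pref = NA_real_
  )
  rbind(sp, ns)
}

#' Generate a synthetic county crop census
#'
#' Each county draws a crop list from a fixed catalog. Specialty acreage is
#' heavy-tailed (lognormal) so a small subset of counties dominates total
#' specialty acreage; a configurable fraction of counties has no specialty
#' crops at all, and a configurable fraction is flagged as
#' disclosure-suppressed (`complete = FALSE`; acreage totals are kept).
#' Specialty crop choice is weighted toward crops whose preferred latitude
#' matches the county's, so neighboring-climate counties share crops.
#'
#' Called by [generate_climate()]; the RNG state is whatever the caller set.
#'
#' @param config a [synthetic_config()].
#' @param county_map data.frame with `cell_id`, `county_id` columns.
#' @param catalog crop catalog data.frame (`crop`, `group`, `pref`).
#' @return data.frame with `county_id`, `crop`, `group`, `acres`,
#'   `complete`.
#' @export
generate_crop_census <- function(config, county_map,
                                 catalog = crop_catalog()) {
  if (nrow(catalog) == 0L) stop("empty crop catalog")
  cells <- cell_parameters(config)
  rowfrac <- tapply(cells$row_frac[county_map$cell_id],
                    county_map$county_id, mean)
  counties <- sort(unique(county_map$county_id))
  sp_cat <- catalog[catalog$group %in% SPECIALTY_GROUPS, , drop = FALSE]
  ns_cat <- catalog[!(catalog$group %in% SPECIALTY_GROUPS), , drop = FALSE]
  out <- vector("list", length(counties))
  for (i in seq_along(counties)) {
    cid <- counties[i]
    rows <- list()
    if (nrow(ns_cat) > 0) {
      n_ns <- sample(seq_len(min(3, nrow(ns_cat))), 1)
      pick <- sample(nrow(ns_cat), n_ns)
      rows$ns <- data.frame(county_id = cid, crop = ns_cat$crop[pick],
                            group = ns_cat$group[pick],
                            acres = rlnorm(n_ns, log(5000), 1))
    }
    if (runif(1) < config$specialty_fraction && nrow(sp_cat) > 0) {
      total <- rlnorm(1, log(2000), 1.8)
      n_sp <- sample(2:min(6, nrow(sp_cat)), 1)
      w <- exp(-((sp_cat$pref - rowfrac[as.character(cid)])^2) /
                 (2 * 0.25^2)) + 1e-6
      pick <- sample(nrow(sp_cat), n_sp, prob = w)
      shares <- rgamma(n_sp, 1)
      rows$sp <- data.frame(county_id = cid, crop = sp_cat$crop[pick],
                            group = sp_cat$group[pick],
                            acres = total * shares / sum(shares))
    }
    df <- do.call(rbind, rows)
    df$complete <- runif(1) >= config$suppressed_fraction
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
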