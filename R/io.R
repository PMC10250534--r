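.datatable.aware <- TRUE

# Plain-text IO contracts. All weather tables are long-form CSV:
#   cell_id, date (YYYY-DDD ordinal, leapless 365-day years), tmax_c,
#   tmin_c, prcp_mm  [+ scenario, gcm for future data]
# These same schemas are the read contracts for real data.

weather_table <- function(block, scenario = NA_character_,
                          gcm = NA_character_) {
  d <- dim(block$tmax)
  n_cells <- d[1]; n_years <- d[3]
  dt <- data.table::data.table(
    cell_id = rep(seq_len(n_cells), times = 365 * n_years),
    date = rep(sprintf("%04d-%03d", rep(block$years, each = 365),
                       rep(seq_len(365), times = n_years)),
               each = n_cells),
    tmax_c = as.vector(block$tmax),
    tmin_c = as.vector(block$tmin),
    prcp_mm = as.vector(block$prcp))
  if (!is.na(scenario)) dt[, c("scenario", "gcm") := list(scenario, gcm)]
  dt
}

table_to_block <- function(dt) {
  yr <- as.integer(substr(dt$date, 1, 4))
  doy <- as.integer(substr(dt$date, 6, 8))
  years <- sort(unique(yr))
  cells <- sort(unique(dt$cell_id))
  dims <- c(length(cells), 365L, length(years))
  idx <- cbind(match(dt$cell_id, cells), doy, match(yr, years))
  mk <- function(v) { a <- array(NA_real_, dims); a[idx] <- v; a }
  list(tmax = mk(dt$tmax_c), tmin = mk(dt$tmin_c), prcp = mk(dt$prcp_mm),
       years = years)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the long-form weather CSVs, the land-use, county-map, crop
#' census and planted-truth tables to `dir`. The schemas double as the
#' pipeline's read contracts for real data.
#'
#' @param dataset an `analog_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(x, name) {
    p <- file.path(dir, name)
    data.table::fwrite(x, p)
    paths <<- c(paths, p)
  }
  w(weather_table(dataset$historical), "weather_hist.csv")
  fut <- list()
  for (s in names(dataset$future)) {
    for (g in names(dataset$future[[s]])) {
      fut[[paste(s, g)]] <- weather_table(dataset$future[[s]][[g]], s, g)
    }
  }
  w(data.table::rbindlist(fut), "weather_future.csv")
  w(dataset$landuse, "landuse.csv")
  w(dataset$county_map, "county_map.csv")
  w(dataset$crop_census, "census.csv")
  truth <- if (length(dataset$truth)) {
    data.table::rbindlist(lapply(dataset$truth, as.data.frame))
  } else data.frame(target = integer(0), analog = integer(0))
  w(truth, "truth.csv")
  invisible(paths)
}

#' Read weather tables back into an in-memory dataset skeleton
#'
#' Inverse of [write_dataset()] for the fields the pipeline needs
#' downstream of synthesis.
#'
#' @param dir directory holding the CSVs written by [write_dataset()].
#' @return list with `historical`, `future`, `landuse`, `county_map`,
#'   `crop_census`, `truth`.
#' @export
read_dataset <- function(dir) {
  fread <- data.table::fread
  hist_dt <- fread(file.path(dir, "weather_hist.csv"))
  fut_dt <- fread(file.path(dir, "weather_future.csv"))
  future <- list()
  if (nrow(fut_dt)) {
    for (s in unique(fut_dt$scenario)) {
      future[[s]] <- list()
      for (g in unique(fut_dt$gcm[fut_dt$scenario == s])) {
        future[[s]][[g]] <-
          table_to_block(fut_dt[fut_dt$scenario == s & fut_dt$gcm == g, ])
      }
    }
  }
  list(historical = table_to_block(hist_dt), future = future,
       landuse = as.data.frame(fread(file.path(dir, "landuse.csv"))),
       county_map = as.data.frame(fread(file.path(dir, "county_map.csv"))),
       crop_census = as.data.frame(fread(file.path(dir, "census.csv"))),
       truth = as.data.frame(fread(file.path(dir, "truth.csv"))))
}

records_table <- function(records, mode) {
  cbind(mode = mode, records)
}

matches_table <- function(matches) {
  rows <- lapply(matches, function(m) {
    if (length(m$analog_ids) == 0L) {
      return(data.frame(target_id = m$target_id, scenario = m$scenario,
                        analog_id = NA_character_,
                        match_fraction = NA_real_, max_flag = FALSE,
                        category = m$category))
    }
    data.frame(target_id = m$target_id, scenario = m$scenario,
               analog_id = m$analog_ids,
               match_fraction = m$match_fractions,
               max_flag = !is.na(m$match_fractions) &
                 m$match_fractions == m$max_match_fraction &
                 m$analog_ids == m$best_analog_id,
               category = m$category)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

county_year_table <- function(run) {
  rows <- list()
  for (mode in names(run$profiles)) {
    for (cid in names(run$profiles[[mode]])) {
      p <- run$profiles[[mode]][[cid]]
      long <- expand.grid(year = as.integer(rownames(p$icv_series)),
                          variable = p$variable_names,
                          stringsAsFactors = FALSE)
      long$value <- as.vector(p$icv_series)
      rows[[paste(mode, cid)]] <- cbind(
        mode = mode, county_id = cid, scenario = "historical", gcm = "obs",
        long)
    }
  }
  data.table::rbindlist(rows)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(x, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(x, p)
    paths <<- c(paths, p)
  }
  for (mode in names(run$records)) {
    w(records_table(run$records[[mode]], mode),
      sprintf("distances_%s.csv", mode))
    w(run$consensus[[mode]]$members, sprintf("consensus_%s.csv", mode))
  }
  w(matches_table(run$matches), "matches.csv")
  w(county_year_table(run), "county_year.csv")
  w(run$targets, "targets.csv")
  if (!is.null(run$overlap)) w(run$overlap, "overlap.csv")

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(region_pct = run$report$region_pct,
         match_bins = run$report$match_bins,
         audit = run$audit),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, report_path)

  manifest_path <- file.path(out_dir, "manifest.json")
  cfg <- run$config
  jsonlite::write_json(
    list(package_version = as.character(packageVersion("agroanalogs")),
         r_version = as.character(getRversion()),
         seed = cfg$synthetic$seed,
         grid_shape = cfg$synthetic$grid_shape,
         n_counties = cfg$synthetic$n_counties,
         n_gcms = cfg$synthetic$n_gcms,
         scenarios = cfg$synthetic$scenarios,
         variable_mode = cfg$variable_mode,
         sigma_accept = cfg$sigma_accept, sigma_novel = cfg$sigma_novel,
         consensus_m = if (is.null(cfg$consensus_m))
           consensus_threshold(cfg$synthetic$n_gcms) else cfg$consensus_m,
         counts = run$audit,
         files = basename(paths)),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(paths, manifest_path)
}
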