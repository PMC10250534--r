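#' Pipeline configuration
#'
#' Bundles everything one end-to-end analog run needs: the synthetic world
#' (or data loaded through the CLI read contracts), the variable mode
#' (`context` = 5 derived agro-climatic variables, `generic` = 8 seasonal
#' temperature/precipitation variables, `both` = run the two and compare
#' their analog sets), the sigma classification thresholds, the consensus
#' threshold, and output options.
#'
#' @param synthetic a [synthetic_config()] describing the input world.
#' @param variable_mode `"context"`, `"generic"` or `"both"`.
#' @param sigma_accept,sigma_novel classification thresholds
#'   (`0 < sigma_accept < sigma_novel`).
#' @param consensus_m consensus threshold; `NULL` means
#'   [consensus_threshold()] of the ensemble size.
#' @param coverage cumulative specialty-acreage share that defines the
#'   target counties (default 0.99).
#' @param ag_threshold inclusive agricultural-fraction cutoff for
#'   [build_ag_mask()] (default 1/8).
#' @param thresholds a [metric_thresholds()] object.
#' @param sensitivity also recompute consensus for m in {3, 5, 7, 10}
#'   (those valid for the ensemble size; the spec contract rejects
#'   m > n_gcms).
#' @param out_dir directory for CSV/JSON outputs, or `NULL` for an
#'   in-memory run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic,
                            variable_mode = c("context", "generic", "both"),
                            sigma_accept = 2, sigma_novel = 4,
                            consensus_m = NULL,
                            coverage = 0.99,
                            ag_threshold = 1 / 8,
                            thresholds = metric_thresholds(),
                            sensitivity = FALSE,
                            out_dir = NULL) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  variable_mode <- match.arg(variable_mode)
  if (!(sigma_accept > 0 && sigma_accept < sigma_novel)) {
    stop("need 0 < sigma_accept < sigma_novel")
  }
  if (!is.null(consensus_m) && consensus_m < 1) stop("consensus_m must be >= 1")
  structure(
    list(synthetic = synthetic, variable_mode = variable_mode,
         sigma_accept = sigma_accept, sigma_novel = sigma_novel,
         consensus_m = consensus_m, coverage = coverage,
         ag_threshold = ag_threshold, thresholds = thresholds,
         sensitivity = sensitivity, out_dir = out_dir),
    class = "pipeline_config"
  )
}

# drop the first (incomplete chill season) year for context vectors
trim_mode_years <- function(values, years, mode) {
  if (mode == "context") {
    values <- values[, -1L, , drop = FALSE]
    years <- years[-1L]
  }
  list(values = values, years = years)
}

# Historical county profiles for one mode. Ridge warnings are collected
# rather than emitted one by one; their count is attached as an attribute.
county_profiles <- function(dataset, mode, ag_threshold = 1 / 8,
                            thresholds = metric_thresholds()) {
  mask <- build_ag_mask(dataset$landuse, ag_threshold)
  vals <- climate_vectors(dataset$historical, mode, thresholds)
  tr <- trim_mode_years(vals, dataset$historical$years, mode)
  agg <- aggregate_counties(tr$values, dataset$county_map, mask)
  n_ridge <- 0L
  profiles <- lapply(names(agg), function(cid) {
    yearly <- agg[[cid]]
    rownames(yearly) <- tr$years
    withCallingHandlers(
      build_profile(yearly, county_id = cid),
      warning = function(w) {
        if (grepl("ridge", conditionMessage(w))) {
          n_ridge <<- n_ridge + 1L
          invokeRestart("muffleWarning")
        }
      })
  })
  names(profiles) <- names(agg)
  attr(profiles, "excluded") <- attr(agg, "excluded")
  attr(profiles, "n_ridge") <- n_ridge
  profiles
}

# Future county normals [[scenario]][[gcm]] -> matrix [county, k].
# Only the normal is kept: no future ICV is ever computed (structural
# invariant of the method).
future_county_normals <- function(dataset, mode, ag_threshold = 1 / 8,
                                  thresholds = metric_thresholds()) {
  mask <- build_ag_mask(dataset$landuse, ag_threshold)
  out <- list()
  for (s in names(dataset$future)) {
    out[[s]] <- list()
    for (g in names(dataset$future[[s]])) {
      blk <- dataset$future[[s]][[g]]
      vals <- climate_vectors(blk, mode, thresholds)
      tr <- trim_mode_years(vals, blk$years, mode)
      agg <- aggregate_counties(tr$values, dataset$county_map, mask)
      normals <- t(vapply(agg, colMeans,
                          numeric(length(variable_names(mode)))))
      rownames(normals) <- names(agg)
      out[[s]][[g]] <- normals
    }
  }
  out
}

run_stage <- function(name, expr, cleanup = NULL) {
  tryCatch(expr, error = function(e) {
    if (!is.null(cleanup)) cleanup()
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analog pipeline
#'
#' Executes synthesize -> derive metrics -> aggregate to counties ->
#' distances and sigma dissimilarity -> multi-GCM consensus -> crop-mix
#' matching -> summary report. All randomness derives from the synthetic
#' config's seed; the same config gives identical results (and identical
#' output files when `out_dir` is set). A failing stage aborts with the
#' stage named and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return object of class `analog_run`: dataset, crop mixes, selected
#'   targets, per-mode profiles/records/consensus, crop `matches`,
#'   `overlap` (when both modes ran), `report`, `audit` and `manifest`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  written <- character(0)
  cleanup <- function() if (length(written)) unlink(written)
  say <- function(...) if (!quiet) message(sprintf(...))

  dataset <- run_stage("synth", generate_climate(config$synthetic), cleanup)
  say("synth: %d cells, %d counties", nrow(dataset$cells),
      config$synthetic$n_counties)

  modes <- if (config$variable_mode == "both") c("context", "generic") else
    config$variable_mode

  crop_mixes <- run_stage("cropcode", code_specialty(dataset$crop_census),
                          cleanup)
  targets_df <- run_stage("targets",
                          select_targets(crop_mixes, config$coverage),
                          cleanup)

  profiles <- list(); future_normals <- list()
  records <- list(); consensus <- list(); audit <- list()
  for (mode in modes) {
    profiles[[mode]] <- run_stage(
      paste0("aggregate-", mode),
      suppressMessages(county_profiles(dataset, mode, config$ag_threshold,
                                       config$thresholds)),
      cleanup)
    future_normals[[mode]] <- run_stage(
      paste0("metrics-", mode),
      suppressMessages(future_county_normals(dataset, mode,
                                             config$ag_threshold,
                                             config$thresholds)),
      cleanup)
    pool_ids <- names(profiles[[mode]])
    target_ids <- intersect(as.character(targets_df$county_id), pool_ids)
    records[[mode]] <- run_stage(
      paste0("analogs-", mode),
      compute_distances(profiles[[mode]], future_normals[[mode]],
                        target_ids = target_ids,
                        accept = config$sigma_accept,
                        novel = config$sigma_novel),
      cleanup)
    m <- if (is.null(config$consensus_m)) {
      consensus_threshold(config$synthetic$n_gcms)
    } else config$consensus_m
    consensus[[mode]] <- run_stage(
      paste0("consensus-", mode),
      consensus_analogs(records[[mode]], m = m,
                        novel = config$sigma_novel),
      cleanup)
    audit[[mode]] <- list(
      n_records = nrow(records[[mode]]),
      expected = comparison_count(length(target_ids),
                                  config$synthetic$n_gcms,
                                  length(config$synthetic$scenarios),
                                  length(pool_ids)),
      n_targets = length(target_ids), n_candidates = length(pool_ids),
      n_gcms = config$synthetic$n_gcms,
      n_scenarios = length(config$synthetic$scenarios))
    say("%s: %d distance records", mode, nrow(records[[mode]]))
  }

  primary <- modes[1]
  matches <- run_stage("cropmatch", {
    res <- list()
    for (s in config$synthetic$scenarios) {
      for (tid in unique(records[[primary]]$target_id)) {
        res[[paste(tid, s, sep = "|")]] <-
          max_match(tid, consensus[[primary]], crop_mixes, s)
      }
    }
    res
  }, cleanup)

  overlap <- NULL
  if (length(modes) == 2L) {
    overlap <- run_stage("overlap", {
      rows <- list(); i <- 0L
      for (s in config$synthetic$scenarios) {
        for (tid in unique(records[[1]]$target_id)) {
          a <- consensus_ids(consensus$context, tid, s)
          b <- consensus_ids(consensus$generic, tid, s)
          ov <- analogset_overlap(a, b)
          i <- i + 1L
          rows[[i]] <- data.frame(target_id = tid, scenario = s,
                                  overlap = as.numeric(ov),
                                  both_empty = attr(ov, "both_empty"))
        }
      }
      do.call(rbind, rows)
    }, cleanup)
  }

  regions <- unique(dataset$county_map[, c("county_id", "region")])
  report <- run_stage("report",
                      summarize_analogs(matches, regions, overlap, audit),
                      cleanup)

  sensitivity <- NULL
  if (isTRUE(config$sensitivity)) {
    ms <- Filter(function(m) m <= config$synthetic$n_gcms, c(3, 5, 7, 10))
    sensitivity <- lapply(setNames(ms, paste0("m", ms)), function(m) {
      cs <- consensus_analogs(records[[primary]], m = m,
                              novel = config$sigma_novel)
      list(m = m, n_members = nrow(cs$members),
           sizes = setNames(cs$targets$n_analogs,
                            paste(cs$targets$target_id,
                                  cs$targets$scenario, sep = "|")))
    })
  }

  run <- structure(
    list(config = config, dataset = dataset, crop_mixes = crop_mixes,
         targets = targets_df, profiles = profiles,
         future_normals = future_normals, records = records,
         consensus = consensus, matches = matches, overlap = overlap,
         report = report, audit = audit, sensitivity = sensitivity),
    class = "analog_run")

  if (!is.null(out_dir)) {
    written <- run_stage("write", write_run_outputs(run, out_dir), cleanup)
    run$manifest <- file.path(out_dir, "manifest.json")
  }
  run
}

#' @export
print.analog_run <- function(x, ...) {
  cat(sprintf("<analog_run> %d target(s), modes: %s\n",
              nrow(x$targets), paste(names(x$records), collapse = ", ")))
  for (mode in names(x$audit)) {
    a <- x$audit[[mode]]
    cat(sprintf("  %s: %d records (expected %d)\n", mode, a$n_records,
                a$expected))
  }
  invisible(x)
}

#' Summarize an analog run
#'
#' Region-level percentages of the three analog-existence categories per
#' scenario (summing to 100 per region), the distribution of maximum
#' crop-match fractions against the 20/40/60 percent reporting bins,
#' per-target context-vs-generic analog-set overlap when both modes ran,
#' and the comparison-count audit.
#'
#' @param matches named list of `match_result` objects (`"target|scenario"`).
#' @param regions data.frame `county_id`, `region`.
#' @param overlap optional data.frame from a both-modes run.
#' @param audit per-mode audit list.
#' @return object of class `analog_report`.
#' @export
summarize_analogs <- function(matches, regions, overlap = NULL,
                              audit = NULL) {
  if (length(matches) == 0L) stop("no match results to summarize")
  df <- data.frame(
    target_id = vapply(matches, function(m) as.character(m$target_id),
                       character(1)),
    scenario = vapply(matches, function(m) m$scenario, character(1)),
    category = vapply(matches, function(m) m$category, character(1)),
    max_match = vapply(matches, function(m) m$max_match_fraction,
                       numeric(1)),
    row.names = NULL)
  reg <- setNames(regions$region, as.character(regions$county_id))
  df$region <- reg[df$target_id]
  cats <- c("has-specialty-analog", "only-nonspecialty-analog", "no-analog")

  region_pct <- list()
  for (s in unique(df$scenario)) {
    sub <- df[df$scenario == s, , drop = FALSE]
    tab <- table(factor(sub$region), factor(sub$category, levels = cats))
    pct <- 100 * prop.table(tab, margin = 1)
    region_pct[[s]] <- as.data.frame.matrix(pct)
  }

  match_bins <- list()
  for (s in unique(df$scenario)) {
    mm <- df$max_match[df$scenario == s]
    mm <- mm[!is.na(mm)]
    match_bins[[s]] <- if (length(mm)) {
      c(ge20 = mean(mm >= 0.2) * 100, ge40 = mean(mm >= 0.4) * 100,
        ge60 = mean(mm >= 0.6) * 100, n_scorable = length(mm))
    } else c(ge20 = NA, ge40 = NA, ge60 = NA, n_scorable = 0)
  }

  structure(
    list(targets = df, region_pct = region_pct, match_bins = match_bins,
         overlap = overlap, audit = audit),
    class = "analog_report")
}

#' @export
print.analog_report <- function(x, ...) {
  for (s in names(x$region_pct)) {
    cat(sprintf("scenario %s: category %% by region\n", s))
    print(round(x$region_pct[[s]], 1))
    b <- x$match_bins[[s]]
    cat(sprintf("  max crop match >= 20/40/60%%: %.0f%% / %.0f%% / %.0f%% (n = %d)\n",
                b["ge20"], b["ge40"], b["ge60"], b["n_scorable"]))
  }
  if (!is.null(x$overlap)) {
    cat(sprintf("context-vs-generic overlap: mean %.2f, %d%% zero-overlap\n",
                mean(x$overlap$overlap),
                round(100 * mean(x$overlap$overlap == 0))))
  }
  invisible(x)
}
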