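test_that("config validation enforces the stated invariants", {
  expect_error(synthetic_config(1, grid_shape = c(0, 5)), "positive")
  expect_error(synthetic_config(1, grid_shape = c(2, 2), n_counties = 5),
               "between 1 and")
  expect_error(synthetic_config(1, n_years_hist = 2), ">= 3")
  expect_error(synthetic_config(1, warming_offsets = matrix(Inf, 2, 6)),
               "finite")
  expect_error(synthetic_config(1, planted_pairs = list(c(3, 3))),
               "distinct")
})

test_that("identical seeds give identical datasets", {
  d1 <- generate_climate(tiny_cfg(seed = 5))
  d2 <- generate_climate(tiny_cfg(seed = 5))
  expect_identical(d1, d2)
  d3 <- generate_climate(tiny_cfg(seed = 6))
  expect_false(identical(d1$historical$tmax, d3$historical$tmax))
})

test_that("physical sanity: tmax >= tmin and precip >= 0 everywhere", {
  ds <- generate_climate(tiny_cfg(seed = 2))
  expect_true(all(ds$historical$tmax >= ds$historical$tmin))
  expect_true(all(ds$historical$prcp >= 0))
  for (s in names(ds$future)) for (g in names(ds$future[[s]])) {
    blk <- ds$future[[s]][[g]]
    expect_true(all(blk$tmax >= blk$tmin))
    expect_true(all(blk$prcp >= 0))
  }
})

test_that("zero noise and zero warming make future equal historical", {
  ds <- generate_climate(zero_cfg(seed = 1, warming = FALSE))
  for (s in names(ds$future)) for (g in names(ds$future[[s]])) {
    expect_equal(ds$future[[s]][[g]]$tmax[, , 1],
                 ds$historical$tmax[, , 1])
    expect_equal(ds$future[[s]][[g]]$prcp[, , 1],
                 ds$historical$prcp[, , 1])
  }
})

test_that("precipitation regimes match their stated climatologies", {
  ds <- generate_climate(zero_cfg(seed = 1))
  month_of <- rep(1:12, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  for (cell in c(1L, nrow(ds$cells))) {
    pr <- ds$historical$prcp[cell, , 1]
    monthly <- tapply(pr, month_of, sum)
    if (ds$cells$winter_wet[cell]) {
      share <- sum(monthly[c(10:12, 1:3)]) / sum(monthly)
      expect_gte(share, 0.7)
    } else {
      expect_true(all(abs(monthly / mean(monthly) - 1) <= 0.25))
    }
  }
  expect_true(any(ds$cells$winter_wet) && !all(ds$cells$winter_wet))
})

test_that("county partition covers every cell exactly once", {
  ds <- generate_climate(tiny_cfg(seed = 4))
  cm <- ds$county_map
  expect_setequal(cm$cell_id, ds$cells$cell_id)
  expect_equal(anyDuplicated(cm$cell_id), 0L)
  expect_equal(sort(unique(cm$county_id)), 1:6)
  expect_true(all(table(cm$county_id) >= 1))
  expect_true(all(cm$region %in% c("NW", "NE", "SW", "SE")))
})

test_that("planting validates its preconditions", {
  ds <- generate_climate(tiny_cfg(seed = 1))
  expect_error(plant_known_analog(ds, 2, 2), "distinct")
  expect_error(plant_known_analog(ds, 1, 99), "unknown county")
  ds2 <- plant_known_analog(ds, 1, 4)
  expect_equal(ds2$truth[[1]], list(target = 1, analog = 4))
})

test_that("planting with zero noise zeroes the downstream dissimilarity", {
  # single-cell counties: county aggregation is the identity, so the
  # planted target future equals the analog history exactly
  cfg <- zero_cfg(seed = 2, warming = TRUE, grid_shape = c(3, 3),
                  n_counties = 9, ag_fraction_range = c(0.5, 0.9),
                  planted_pairs = list(c(2, 8)))
  run <- run_pipeline(pipeline_config(cfg, variable_mode = "context"))
  rec <- run$records$context
  sub <- rec[rec$target_id == "2" & rec$candidate_id == "8", ]
  expect_true(nrow(sub) > 0)
  expect_equal(max(sub$sigma), 0)
  expect_true(all(sub$category == "acceptable"))
})

test_that("crop census: suppression and specialty fractions behave", {
  cfg0 <- tiny_cfg(seed = 3, suppressed_fraction = 0)
  cen0 <- generate_climate(cfg0)$crop_census
  expect_true(all(cen0$complete))

  cfg_ns <- tiny_cfg(seed = 3, specialty_fraction = 0)
  mixes <- code_specialty(generate_climate(cfg_ns)$crop_census)
  expect_false(any(vapply(mixes, function(m) m$specialty, logical(1))))
  expect_error(select_targets(mixes), "no specialty")
})

test_that("specialty acreage is heavy-tailed (seeds 0-9)", {
  for (seed in 0:9) {
    cfg <- synthetic_config(seed = seed, grid_shape = c(8, 8),
                            n_counties = 16, n_years_hist = 3,
                            n_years_future = 2, n_gcms = 1,
                            specialty_fraction = 1)
    census <- generate_crop_census(cfg, partition <- data.frame(
      cell_id = 1:64, county_id = rep(1:16, each = 4)))
    sp <- census[census$group %in% c("vegetable", "fruit", "tree nut",
                                     "berry"), ]
    acres <- sort(tapply(sp$acres, sp$county_id, sum), decreasing = TRUE)
    n99 <- match(TRUE, cumsum(acres) / sum(acres) >= 0.99)
    expect_lt(n99, length(acres))
  }
})

test_that("winter-wet and uniform counties separate in precip uniformity", {
  # 8x8 grid, 16 counties of half-row width: each county is single-regime
  cfg <- synthetic_config(seed = 1, grid_shape = c(8, 8), n_counties = 16,
                          n_years_hist = 10, n_years_future = 2, n_gcms = 1)
  ds <- generate_climate(cfg)
  profs <- suppressWarnings(suppressMessages(
    agroanalogs:::county_profiles(ds, "context")))
  ww_cells <- ds$cells$winter_wet
  regime <- tapply(ww_cells[ds$county_map$cell_id],
                   ds$county_map$county_id, function(x) mean(x) > 0.5)
  pr_norm <- vapply(profs, function(p) p$normal["precip_range"], numeric(1))
  pr_sd <- vapply(profs, function(p)
    sqrt(p$icv_cov["precip_range", "precip_range"]), numeric(1))
  ids <- names(profs)
  ww <- regime[ids]
  margin <- mean(pr_norm[ww]) - mean(pr_norm[!ww])
  expect_gt(margin, max(pr_sd))
})
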