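test_that("daily GDD follows the clipped-average formula", {
  expect_equal(daily_gdd(20, 10), 15)
  expect_equal(daily_gdd(-5, -10), 0)       # both clipped to base
  expect_equal(daily_gdd(35, 10), 19.72)    # (29.44 + 10)/2 - 0
  expect_equal(daily_gdd(c(20, 35), c(10, 10)), c(15, 19.72))
  expect_error(daily_gdd(10, 20), "tmax < tmin")
})

test_that("annual GDD sums daily GDD over the calendar year", {
  expect_equal(annual_gdd(const_series(20, 10), 2001), 15 * 365)
  expect_equal(annual_gdd(const_series(-5, -10), 2001), 0)
  tx <- matrix(-10, 365, 1); tn <- matrix(-15, 365, 1)
  tx[50, 1] <- 20; tn[50, 1] <- 10
  one_warm <- daily_series(tx, tn, matrix(0, 365, 1), years = 2001)
  expect_equal(annual_gdd(one_warm, 2001), 15)
  expect_error(annual_gdd(const_series(), 1990), "not present")
})

test_that("frost-free season length is the longest frost-free run", {
  expect_equal(frost_free_season_length(const_series(20, 10), 2001), 365)
  expect_equal(frost_free_season_length(const_series(0, -5), 2001), 0)
  tn <- matrix(5, 365, 1); tn[100, 1] <- -1
  s <- daily_series(matrix(20, 365, 1), tn, matrix(0, 365, 1), 2001)
  expect_equal(frost_free_season_length(s, 2001), 265) # max(99, 265)
})

test_that("hourly sine disaggregation hits its stated extremes and mean", {
  expect_equal(disaggregate_hourly(10, 10), rep(10, 24))
  h <- disaggregate_hourly(30, 10)
  expect_equal(h[15 + 1], 30) # peak at 15:00
  expect_equal(h[3 + 1], 10)  # trough at 03:00
  expect_equal(mean(h), 20, tolerance = 1e-12)
  expect_error(disaggregate_hourly(5, 10), "tmax < tmin")
})

test_that("disaggregation conserves the daily mean and bounds (100 random days)", {
  set.seed(42)
  for (i in 1:100) {
    tn <- runif(1, -20, 30); tx <- tn + runif(1, 0, 25)
    h <- disaggregate_hourly(tx, tn)
    expect_lt(abs(mean(h) - (tx + tn) / 2), 1e-9)
    expect_gte(min(h), tn - 1e-9)
    expect_lte(max(h), tx + 1e-9)
  }
})

test_that("heat degree hours accumulate hourly exceedance over JAS", {
  expect_equal(heat_degree_hours(const_series(33, 33), 2001), 1 * 24 * 92)
  expect_equal(heat_degree_hours(const_series(30, 30), 2001), 0)
  # one hot day, rest cold: equals the brute-force sum of the 24 sine values
  tx <- matrix(10, 365, 1); tn <- matrix(5, 365, 1)
  tx[200, 1] <- 34; tn[200, 1] <- 30 # day 200 is in JAS
  s <- daily_series(tx, tn, matrix(0, 365, 1), 2001)
  expect_equal(heat_degree_hours(s, 2001),
               sum(pmax(0, oracle_hourly(34, 30) - 32)))
})

test_that("chill hours count the inclusive 0-7.22 band over Oct-Mar", {
  expect_equal(chill_hours(const_series(5, 5), 2002), 24 * 182)
  expect_equal(chill_hours(const_series(10, 10), 2002), 0)
  # inclusive upper bound: one day exactly at 7.22 degC
  tx <- matrix(20, 365, 2); tn <- matrix(20, 365, 2)
  tx[50, 2] <- 7.22; tn[50, 2] <- 7.22
  s <- daily_series(tx, tn, matrix(0, 365, 2), 2001:2002)
  expect_equal(chill_hours(s, 2002), 24)
  expect_warning(v <- chill_hours(const_series(5, 5), 2001), "incomplete")
  expect_true(is.na(v))
})

test_that("precipitation uniformity is the wettest-driest monthly range", {
  mk <- function(tot) daily_series(matrix(20, 365, 1), matrix(10, 365, 1),
                                   matrix(monthly_precip_days(tot), 365, 1),
                                   2001)
  expect_equal(precipitation_uniformity(mk(rep(50, 12)), 2001), 0)
  expect_equal(precipitation_uniformity(mk(c(100, rep(0, 11))), 2001), 100)
  expect_equal(precipitation_uniformity(mk(seq(10, 120, by = 10)), 2001),
               110)
})

test_that("generic vector gives seasonal means and totals over JFM/AMJ/JAS/OND", {
  v <- generic_vector(const_series(20, 10, prcp = 2), 2001)
  expect_equal(unname(v[1:4]), rep(15, 4))
  expect_equal(unname(v[5:8]), 2 * c(90, 91, 92, 92))
  expect_equal(sum(c(90, 91, 92, 92)), 365)
  # JFM-only rain leaves the other three seasons at zero
  pr <- matrix(0, 365, 1); pr[1:90, 1] <- 1
  s <- daily_series(matrix(20, 365, 1), matrix(10, 365, 1), pr, 2001)
  expect_equal(unname(generic_vector(s, 2001)[5:8]), c(90, 0, 0, 0))
})

test_that("context vector composes the five indices and rejects year one", {
  s <- const_series(20, 10, prcp = 2, ny = 2)
  v <- context_vector(s, 2002)
  expect_named(v, c("gdd", "season_length", "hdh", "chill", "precip_range"))
  expect_equal(unname(v), c(15 * 365, 365, 0, 0,
                            precipitation_uniformity(s, 2002)))
  expect_error(context_vector(s, 2001), "rejected")
})

test_that("order-of-days invariances hold", {
  set.seed(7)
  tn <- runif(365, -5, 15); tx <- tn + runif(365, 1, 15)
  pr <- rgamma(365, 1, 0.5)
  s <- daily_series(matrix(tx, 365, 1), matrix(tn, 365, 1),
                    matrix(pr, 365, 1), 2001)
  # permute days *within each month*: GDD and precip_range are unchanged
  month_of <- rep(1:12, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  perm <- unlist(lapply(split(seq_len(365), month_of), sample))
  s2 <- daily_series(matrix(tx[perm], 365, 1), matrix(tn[perm], 365, 1),
                     matrix(pr[perm], 365, 1), 2001)
  expect_equal(annual_gdd(s2, 2001), annual_gdd(s, 2001))
  expect_equal(precipitation_uniformity(s2, 2001),
               precipitation_uniformity(s, 2001))
})

test_that("GDD and HDH are monotone under uniform warming", {
  set.seed(11)
  for (i in 1:10) {
    tn <- runif(365, -10, 20); tx <- tn + runif(365, 0, 15)
    s0 <- daily_series(matrix(tx, 365, 1), matrix(tn, 365, 1),
                       matrix(0, 365, 1), 2001)
    s1 <- daily_series(matrix(tx + 1, 365, 1), matrix(tn + 1, 365, 1),
                       matrix(0, 365, 1), 2001)
    expect_gte(annual_gdd(s1, 2001), annual_gdd(s0, 2001))
    expect_gte(heat_degree_hours(s1, 2001), heat_degree_hours(s0, 2001))
  }
})

test_that("bulk climate_vectors agrees with the per-series operations", {
  cfg <- tiny_cfg(seed = 3)
  ds <- generate_climate(cfg)
  vals <- climate_vectors(ds$historical, "context")
  gen <- climate_vectors(ds$historical, "generic")
  for (cell in c(1L, 17L, 36L)) {
    s <- daily_series(ds$historical$tmax[cell, , ],
                      ds$historical$tmin[cell, , ],
                      ds$historical$prcp[cell, , ],
                      ds$historical$years)
    for (yi in c(2L, 5L)) {
      y <- ds$historical$years[yi]
      expect_equal(unname(vals[cell, yi, ]),
                   unname(context_vector(s, y)), tolerance = 1e-10)
      expect_equal(unname(gen[cell, yi, ]),
                   unname(generic_vector(s, y)), tolerance = 1e-10)
    }
  }
})
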