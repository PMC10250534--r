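test_that("Mahalanobis distance: identity reduction and oracle equivalence", {
  expect_equal(mahalanobis_distance(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_distance(c(3, 4), c(0, 0), diag(2)), 5)
  expect_error(mahalanobis_distance(c(1, 2, 3), c(0, 0), diag(2)),
               "dimension mismatch")
  expect_error(mahalanobis_distance(c(NA, 1), c(0, 0), diag(2)),
               "non-finite")
  set.seed(13)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    A <- matrix(rnorm(k * k), k)
    C <- crossprod(A) + diag(0.5, k)
    d <- rnorm(k)
    oracle <- sqrt(drop(t(d) %*% solve(C) %*% d)) # explicit inverse
    expect_equal(mahalanobis_distance(d, rep(0, k), C), oracle,
                 tolerance = 1e-10)
  }
})

test_that("sigma dissimilarity maps chi percentiles as stated", {
  expect_equal(as.numeric(sigma_dissimilarity(0, 5)), 0)
  x <- seq(0, 8, by = 0.25)
  expect_identical(as.numeric(sigma_dissimilarity(x, 1)), x) # dof 1 identity
  # sqrt of chi-square(5) 95th percentile (11.0705) maps to the normal
  # 2-sided 95% point 1.95996
  expect_equal(as.numeric(sigma_dissimilarity(3.3272, 5)), 1.95996,
               tolerance = 1e-3)
  expect_error(sigma_dissimilarity(-1, 3), "non-negative")
})

test_that("sigma is strictly increasing below the cap and saturates above", {
  for (dof in c(2, 5, 8)) {
    x <- seq(0.1, 6, by = 0.1)
    s <- as.numeric(sigma_dissimilarity(x, dof))
    expect_true(all(diff(s) > 0))
  }
  big <- sigma_dissimilarity(100, 5)
  expect_equal(as.numeric(big), 10)
  expect_true(attr(big, "saturated"))
})

test_that("classification thresholds are inclusive as printed", {
  expect_equal(as.character(classify_analogs(c(2, 4, 3, 0, 10))),
               c("acceptable", "novel-range", "intermediate",
                 "acceptable", "novel-range"))
  s <- runif(50, 0, 6)
  cl <- classify_analogs(s)
  expect_false(anyNA(cl)) # partition is exhaustive
})

fake_records <- function(accept_gcms, n_gcms = 19) {
  # one target, one candidate, one scenario; candidate acceptable in
  # `accept_gcms` of the GCMs
  gcms <- sprintf("g%02d", seq_len(n_gcms))
  sigma <- rep(3, n_gcms)
  sigma[seq_len(accept_gcms)] <- 1
  data.frame(target_id = "t1", candidate_id = "c1", scenario = "s1",
             gcm = gcms, mahalanobis = sigma, dof = 5, sigma = sigma,
             category = classify_analogs(sigma))
}

test_that("consensus keeps candidates acceptable in at least m GCMs", {
  cs5 <- consensus_analogs(fake_records(5), m = 5)
  expect_equal(nrow(cs5$members), 1L)
  expect_equal(cs5$members$n_gcms_supporting, 5L)
  cs4 <- consensus_analogs(fake_records(4), m = 5)
  expect_equal(nrow(cs4$members), 0L)
  expect_true(cs4$targets$no_analog)
  expect_false(cs4$targets$novel) # sigma 1 < 4 exists
  # m = 1 degenerates to the union of per-GCM acceptable sets
  cs1 <- consensus_analogs(fake_records(1), m = 1)
  expect_equal(nrow(cs1$members), 1L)
  expect_error(consensus_analogs(fake_records(5), m = 0), "consensus m")
  expect_error(consensus_analogs(fake_records(5), m = 20), "consensus m")
})

test_that("consensus sets shrink monotonically in m", {
  set.seed(14)
  recs <- do.call(rbind, lapply(1:8, function(ci) {
    r <- fake_records(sample(0:12, 1), n_gcms = 12)
    r$candidate_id <- paste0("c", ci)
    r
  }))
  sizes <- vapply(c(3, 5, 7, 10), function(m) {
    nrow(consensus_analogs(recs, m = m)$members)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("novel flag requires all candidates beyond 4 sigma in all GCMs", {
  r <- fake_records(0)
  r$sigma <- rep(5, nrow(r)); r$mahalanobis <- r$sigma
  r$category <- classify_analogs(r$sigma)
  cs <- consensus_analogs(r, m = 5)
  expect_true(cs$targets$no_analog)
  expect_true(cs$targets$novel)
})

test_that("analog-set overlap is the Jaccard fraction with flagged empties", {
  expect_equal(as.numeric(analogset_overlap(c("a", "b", "c"),
                                            c("b", "c", "d"))), 0.5)
  expect_equal(as.numeric(analogset_overlap(1:3, 1:3)), 1)
  expect_equal(as.numeric(analogset_overlap(1:3, 4:6)), 0)
  ov <- analogset_overlap(integer(0), integer(0))
  expect_equal(as.numeric(ov), 1)
  expect_true(attr(ov, "both_empty"))
  expect_false(attr(analogset_overlap(1, 1), "both_empty"))
})

test_that("consensus threshold scales the >25% rule", {
  expect_equal(consensus_threshold(19), 5L) # the conventional 5-of-19
  for (n in 4:30) {
    m <- consensus_threshold(n)
    expect_gt(m / n, 0.25)
    expect_lte((m - 1) / n, 0.25 + 1e-12)
  }
  expect_equal(consensus_threshold(6), 2L)
})

test_that("comparison count is the closed-form product", {
  expect_equal(comparison_count(2, 3, 2, 7), 84)
  expect_equal(comparison_count(680, 19, 2, 3001), 77545840)
})

test_that("distances are invariant to rescaling a variable and its ICV", {
  set.seed(15)
  y <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  fut <- c(a = 0.5, b = -0.2, c = 1.1)
  p <- build_profile(y, "c1")
  d0 <- mahalanobis_distance(fut, p$normal, p$icv_cov)
  y2 <- y; y2[, "b"] <- y2[, "b"] * 1000
  fut2 <- fut; fut2["b"] <- fut2["b"] * 1000
  p2 <- build_profile(y2, "c1")
  d1 <- mahalanobis_distance(fut2, p2$normal, p2$icv_cov)
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("compute_distances enumerates every combination once", {
  ds <- generate_climate(tiny_cfg(seed = 6))
  profs <- suppressWarnings(suppressMessages(
    agroanalogs:::county_profiles(ds, "context")))
  fut <- suppressMessages(
    agroanalogs:::future_county_normals(ds, "context"))
  rec <- compute_distances(profs, fut)
  expect_equal(nrow(rec),
               comparison_count(nrow(fut[[1]][[1]]), 2, 2, length(profs)))
  key <- paste(rec$target_id, rec$candidate_id, rec$scenario, rec$gcm)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(rec$dof == 5))
  expect_true(all(rec$sigma >= 0 & rec$mahalanobis >= 0))
  # sigma = 0 iff mahalanobis = 0
  expect_equal(rec$sigma == 0, rec$mahalanobis == 0)
})
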