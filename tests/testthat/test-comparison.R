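mk_profile <- function(sizes, ab, kind = "digital", range = c(50L, 500L))
  trflp_profile(data.frame(size = sizes, abundance = ab), kind = kind,
                size_range = range)

test_that("profile_to_vector bins peaks at 1 bp and renormalizes after the 50 bp cut", {
  p <- mk_profile(c(50L, 500L), c(60, 40))
  v <- profile_to_vector(p)
  expect_length(v, 451L)
  expect_equal(unname(v[c("50", "500")]), c(60, 40))
  expect_equal(sum(v), 100)

  # a sub-50 bp peak is dropped and the rest renormalized
  p2 <- trflp_profile(data.frame(size = c(49L, 100L), abundance = c(20, 80)),
                      size_range = c(1L, 500L))
  v2 <- profile_to_vector(p2)
  expect_equal(unname(v2["100"]), 100)

  p3 <- trflp_profile(data.frame(size = 40L, abundance = 100),
                      size_range = c(1L, 500L))
  expect_error(profile_to_vector(p3), "empty")
})

test_that("cross-correlation recovers exact translations with coefficient 1", {
  v <- numeric(451); names(v) <- 50:500
  v[c(30, 80, 150, 260)] <- c(40, 30, 20, 10)

  same <- cross_correlate(v, v)
  expect_equal(same$optimal_lag, 0L)
  expect_equal(same$max_coefficient, 1.0)

  # digital fragments 5 bp long: evec = dvec translated down by 5 bins
  e <- numeric(451)
  e[c(25, 75, 145, 255)] <- c(40, 30, 20, 10)
  res <- cross_correlate(v, e)
  expect_equal(res$optimal_lag, -5L)
  expect_equal(res$max_coefficient, 1.0)
  expect_equal(res$coefficients[match(res$optimal_lag, res$lags)],
               res$max_coefficient)

  # disjoint support beyond the window: all coefficients 0
  a <- numeric(451); b <- numeric(451)
  a[1] <- 100; b[400] <- 100
  far <- cross_correlate(a, b, max_lag = 20)
  expect_true(all(far$coefficients == 0))

  expect_error(cross_correlate(numeric(451), v), "zero-norm")
})

test_that("shift-recovery is exact for every lag in [-10, 10]", {
  set.seed(808)
  base <- numeric(451)
  base[sample(100:300, 12)] <- runif(12, 1, 20)
  base <- 100 * base / sum(base)
  for (k in -10:10) {
    shifted <- numeric(451)
    idx <- which(base > 0)
    shifted[idx + k] <- base[idx]
    res <- cross_correlate(base, shifted)
    expect_equal(res$optimal_lag, as.integer(k), info = paste("lag", k))
    expect_equal(res$max_coefficient, 1.0, info = paste("lag", k))
  }
})

test_that("cross_correlate equals the brute-force double-loop oracle", {
  set.seed(909)
  for (i in 1:100) {
    d <- numeric(451); e <- numeric(451)
    nd <- sample(3:15, 1); ne <- sample(3:15, 1)
    d[sample(451, nd)] <- runif(nd, 1, 50)
    e[sample(451, ne)] <- runif(ne, 1, 50)
    got <- cross_correlate(d, e, max_lag = 15)
    want <- oracle_xcorr(d, e, max_lag = 15)
    expect_equal(got$coefficients, want$coefficients, info = paste("trial", i))
    expect_true(all(got$coefficients >= 0 & got$coefficients <= 1))
  }
})

test_that("recovered lag is robust to 20% peak-height jitter", {
  set.seed(1010)
  ok <- 0L
  for (trial in 1:100) {
    d <- numeric(451)
    d[sample(60:380, 10)] <- runif(10, 2, 30)
    k <- sample(-6:-3, 1)
    e <- numeric(451)
    idx <- which(d > 0)
    e[idx + k] <- d[idx] * runif(length(idx), 0.8, 1.2)
    if (cross_correlate(d, e)$optimal_lag == k) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("apply_shift moves sizes by the lag and drops out-of-range peaks", {
  p <- mk_profile(c(219L, 400L), c(80, 20))
  s <- apply_shift(p, -5L)
  expect_equal(s$peaks$size, c(214L, 395L))
  expect_equal(s$peaks$abundance, c(80, 20))

  expect_identical(apply_shift(p, 0L), p)

  edge <- mk_profile(c(52L, 219L), c(10, 90))
  expect_warning(s2 <- apply_shift(edge, -5L), "dropped")
  expect_equal(s2$peaks$size, 214L)
  expect_equal(s2$peaks$abundance, 100)
})

test_that("peak matching is greedy-nearest within tolerance, each peak used once", {
  ep <- mk_profile(c(214L, 300L), c(50, 50), kind = "experimental")
  dp <- mk_profile(c(214L, 302L), c(50, 50))
  m <- match_peaks(ep, dp, tolerance = 1L)
  expect_equal(m$matches$etrf_size, 214L)
  expect_equal(m$matches$distance, 0L)
  expect_equal(m$unmatched_etrfs, 300L)   # nearest digital peak is 2 bp away
  expect_equal(m$unmatched_dtrfs, 302L)
  expect_equal(m$percent_affiliated, 50)

  identical_sets <- match_peaks(ep, mk_profile(c(214L, 300L), c(30, 70)))
  expect_equal(identical_sets$percent_affiliated, 100)

  # tie at equal distance resolves to the smaller digital size
  ep2 <- mk_profile(100L, 100, kind = "experimental")
  dp2 <- mk_profile(c(99L, 101L), c(50, 50))
  m2 <- match_peaks(ep2, dp2)
  expect_equal(m2$matches$shifted_dtrf_size, 99L)
})

test_that("mirror table spans the window with clipped display columns", {
  ep <- mk_profile(c(100L, 200L), c(88, 12), kind = "experimental")
  dp <- mk_profile(c(100L, 200L), c(12, 88))
  md <- mirror_data(ep, dp, clip = 5)
  expect_equal(md$size, 50:500)
  r100 <- md[md$size == 100L, ]
  expect_equal(r100$e_abundance, 88)
  expect_equal(r100$e_display, 5)
  expect_true(r100$e_clipped)
  # identical profiles give a symmetric table
  ep2 <- mk_profile(c(120L, 240L), c(50, 50), kind = "experimental")
  md2 <- mirror_data(ep2, mk_profile(c(120L, 240L), c(50, 50)))
  expect_equal(md2$e_abundance, md2$d_abundance)
})
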