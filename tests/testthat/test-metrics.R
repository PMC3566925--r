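mk_uniform <- function(k) trflp_profile(
  data.frame(size = seq(60L, by = 5L, length.out = k), abundance = rep(100 / k, k)))

test_that("richness and Shannon H' follow their closed forms", {
  for (k in c(1L, 10L, 42L)) {
    idx <- profile_indices(mk_uniform(k))
    expect_equal(idx$richness, k)
    expect_equal(idx$shannon, log(k), tolerance = 1e-12)
  }
  two <- trflp_profile(data.frame(size = c(100L, 200L), abundance = c(90, 10)))
  expect_equal(profile_indices(two)$shannon, -(0.9 * log(0.9) + 0.1 * log(0.1)),
               tolerance = 1e-12)
  expect_equal(round(profile_indices(two)$shannon, 4), 0.3251)
})

test_that("H' is permutation-invariant, maximal when uniform, bounded by ln richness", {
  set.seed(123)
  for (i in 1:20) {
    k <- sample(2:30, 1)
    ab <- runif(k); ab <- 100 * ab / sum(ab)
    sizes <- sort(sample(50:500, k))
    p1 <- trflp_profile(data.frame(size = sizes, abundance = ab))
    perm <- sample(k)
    p2 <- trflp_profile(data.frame(size = sizes[perm], abundance = ab[perm]))
    i1 <- profile_indices(p1)
    expect_equal(i1$shannon, profile_indices(p2)$shannon)
    expect_lte(i1$shannon, log(i1$richness) + 1e-12)
    expect_lte(i1$shannon, profile_indices(mk_uniform(k))$shannon + 1e-12)
  }
})

test_that("shannon index agrees with vegan's on random profiles", {
  skip_if_not_installed("vegan")
  set.seed(321)
  for (i in 1:10) {
    k <- sample(3:40, 1)
    ab <- runif(k); ab <- 100 * ab / sum(ab)
    p <- trflp_profile(data.frame(size = sort(sample(50:500, k)), abundance = ab))
    expect_equal(profile_indices(p)$shannon,
                 unname(vegan::diversity(ab, index = "shannon")),
                 tolerance = 1e-10)
  }
})

test_that("density report bins distinct T-RFs per 50-bp class with cumulative curve", {
  p <- trflp_profile(data.frame(size = c(60L, 70L, 220L), abundance = c(20, 30, 50)))
  rep1 <- density_report(p)
  cl <- rep1$classes
  expect_equal(cl$count[cl$lower == 50], 2L)
  expect_equal(cl$count[cl$lower == 200], 1L)
  expect_equal(tail(cl$cumulative, 1), 3L)
  expect_equal(tail(cl$cumulative, 1), rep1$indices$richness)
  expect_equal(sum(cl$count), rep1$indices$richness)

  # a T-RF of exactly 500 bp falls in the final class
  p500 <- trflp_profile(data.frame(size = c(100L, 500L), abundance = c(50, 50)))
  cl500 <- density_report(p500)$classes
  expect_equal(cl500$count[cl500$lower == 450], 1L)
})

test_that("enzyme screening ranks enzymes and handles non-cutting enzymes", {
  # references built so HaeIII cuts everything and TaqI nothing
  base <- strrep("ACG", 140)  # no GGCC, no TCGA
  seqs <- paste0(substr(base, 1, 100), "GGCC", substr(base, 101, 420))
  cl <- reads_as_clusters(make_reads(rep(seqs, 5), ids = sprintf("r%d", 1:5)))
  scr <- screen_enzymes(cl, enzymes = restriction_enzymes()[c("HaeIII", "TaqI")])
  expect_equal(scr$ranking$richness[scr$ranking$enzyme == "HaeIII"], 1L)
  expect_equal(scr$ranking$richness[scr$ranking$enzyme == "TaqI"], 0L)
  expect_null(scr$profiles$TaqI)
  expect_error(screen_enzymes(cl, enzymes = list()), "empty enzyme list")

  # determinism: same input, same reports
  scr2 <- screen_enzymes(cl, enzymes = restriction_enzymes()[c("HaeIII", "TaqI")])
  expect_identical(scr$ranking, scr2$ranking)
})

test_that("per-enzyme class counts match a naive per-read scan on random data", {
  set.seed(555)
  seqs <- random_dna(60, 400)
  cl <- reads_as_clusters(make_reads(seqs))
  scr <- screen_enzymes(cl, enzymes = restriction_enzymes()[c("HaeIII", "MspI")])
  for (nm in c("HaeIII", "MspI")) {
    e <- restriction_enzymes()[[nm]]
    sizes <- vapply(seqs, function(s) {
      idx <- oracle_first_site(s, e$recognition)
      if (is.na(idx)) NA_integer_ else idx + e$cut_offset
    }, integer(1), USE.NAMES = FALSE)
    want <- sort(unique(sizes[!is.na(sizes)]))
    got <- scr$profiles[[nm]]$peaks$size
    expect_equal(got, want, info = nm)
    # class counts recompute from the oracle sizes
    oracle_counts <- tabulate(pmin(want %/% 50L, 9L) + 1L, nbins = 10L)
    expect_equal(scr$reports[[nm]]$classes$count, oracle_counts, info = nm)
  }
})

test_that("denoising reduces fingerprint richness on noisy reads", {
  tc <- toy_community(seed = 60, read_count = 150, sub = 0.01, hp = 0.05)
  raw_cl <- reads_as_clusters(tc$sim$reads)
  den_cl <- denoise_cluster(tc$sim$reads)
  raw_p <- build_profile(digest_dataset(raw_cl), size_range = c(1L, 500L))
  den_p <- build_profile(digest_dataset(den_cl), size_range = c(1L, 500L))
  expect_lte(profile_indices(den_p)$richness, profile_indices(raw_p)$richness)
})
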