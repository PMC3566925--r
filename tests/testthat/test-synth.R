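test_that("reference generator pins restriction sites so true fragment sizes are known", {
  ref <- make_reference_db(n_taxa = 5, length = 420,
                           site_positions = c(80L, 120L, 160L, 200L, 240L), seed = 5)
  expect_equal(ref$truth$trf_size, c(82L, 122L, 162L, 202L, 242L))
  # the pinned site really is the first occurrence in each reference
  for (i in 1:5)
    expect_equal(first_cut(ref$db$sequence[i], restriction_enzymes()$HaeIII),
                 ref$truth$trf_size[i])
  # seed-determinism
  ref2 <- make_reference_db(n_taxa = 5, length = 420,
                            site_positions = c(80L, 120L, 160L, 200L, 240L), seed = 5)
  expect_identical(ref$db$sequence, ref2$db$sequence)
  # taxonomy strings are rank-complete
  expect_true(all(grepl("^P:.*;C:.*;O:.*;F:.*;G:.*;S:", ref$db$taxonomy)))
  expect_error(make_reference_db(n_taxa = 2, length = 420,
                                 site_positions = c(100L, 1000L), seed = 1),
               "outside")
})

test_that("read simulator hits its abundance and substitution targets", {
  ref <- make_reference_db(n_taxa = 2, length = 480, seed = 31)
  spec <- community_spec(ref$db, c(0.9, 0.1), read_count = 1000,
                         substitution_rate = 0, homopolymer_indel_rate = 0,
                         seed = 32)
  sim <- simulate_reads(spec)
  n1 <- sum(sim$truth$accession == ref$db$accession[1])
  se <- sqrt(1000 * 0.9 * 0.1)
  expect_lt(abs(n1 - 900), 3 * se)

  # per-read substitution count ~ Binomial(length, rate)
  spec2 <- community_spec(ref$db, c(1, 0), read_count = 500,
                          substitution_rate = 0.01, homopolymer_indel_rate = 0,
                          length_range = c(400L, 400L), seed = 42)
  sim2 <- simulate_reads(spec2)
  edits <- vapply(seq_len(500), function(i) {
    a <- strsplit(sim2$reads$sequence[i], "")[[1]]
    b <- strsplit(substr(ref$db$sequence[1], 1, 400), "")[[1]]
    sum(a != b)
  }, numeric(1))
  expect_lt(abs(mean(edits) - 400 * 0.01), 3 * sqrt(400 * 0.01 * 0.99 / 500))
  # edited bases carry low qualities, clean bases high ones
  expect_true(all(vapply(sim2$reads$quality, function(q) all(q %in% c(10L, 40L)),
                         logical(1))))

  # no-noise limit: reads are exact reference prefixes
  spec0 <- community_spec(ref$db, c(0.5, 0.5), read_count = 50,
                          substitution_rate = 0, homopolymer_indel_rate = 0,
                          seed = 7)
  sim0 <- simulate_reads(spec0)
  src <- match(sim0$truth$accession, ref$db$accession)
  expect_true(all(vapply(seq_len(50), function(i)
    startsWith(ref$db$sequence[src[i]], sim0$reads$sequence[i]), logical(1))))

  # determinism
  expect_identical(simulate_reads(spec)$reads$sequence, sim$reads$sequence)
})

test_that("derived eT-RFLP applies drift, detection floor and renormalization", {
  ref <- make_reference_db(n_taxa = 3, length = 420,
                           site_positions = c(100L, 150L, 200L), seed = 8)
  ab <- c(0.57, 0.40, 0.03)
  ep <- derive_etrflp(ref$truth, ab, drift = 5, detection_floor = 0)
  expect_equal(ep$peaks$size, ref$truth$trf_size - 5L)
  expect_equal(ep$peaks$abundance, 100 * ab)

  # drift 0, no floor: eT-RFLP equals the expected digital profile
  ep0 <- derive_etrflp(ref$truth, ab, drift = 0)
  expect_equal(ep0$peaks$size, ref$truth$trf_size)

  # a 3% peak below a 5% floor disappears and the rest renormalizes
  epf <- derive_etrflp(ref$truth, ab, drift = 5, detection_floor = 5)
  expect_equal(nrow(epf$peaks), 2L)
  expect_equal(epf$peaks$abundance, 100 * c(0.57, 0.40) / 0.97)

  # peaks drifting below 50 bp are dropped with a warning
  ref2 <- make_reference_db(n_taxa = 2, length = 420,
                            site_positions = c(50L, 150L), seed = 9)
  expect_warning(ep2 <- derive_etrflp(ref2$truth, c(0.5, 0.5), drift = 5),
                 "dropped")
  expect_equal(ep2$peaks$size, 147L)
})

test_that("noiseless end-to-end run aligns at the injected drift with coefficient 1", {
  ref <- make_reference_db(n_taxa = 5, length = 480, seed = 13)
  ab <- c(0.35, 0.25, 0.2, 0.12, 0.08)
  sim <- simulate_reads(community_spec(ref$db, ab, read_count = 100,
                                       substitution_rate = 0,
                                       homopolymer_indel_rate = 0, seed = 14))
  real_ab <- realized_abundances(sim, ref$db)
  ep <- derive_etrflp(ref$truth, real_ab, drift = 5)
  cl <- denoise_cluster(sim$reads)
  mp <- map_clusters(cl, ref$db)
  dg <- digest_dataset(cl, mp$hits)
  dp <- build_profile(dg)
  xc <- cross_correlate(profile_to_vector(dp), profile_to_vector(ep))
  expect_equal(xc$optimal_lag, -5L)
  expect_equal(xc$max_coefficient, 1.0)
  shifted <- apply_shift(dp, xc$optimal_lag)
  m <- match_peaks(ep, shifted)
  expect_equal(m$percent_affiliated, 100)
})
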