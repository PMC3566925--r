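test_that("first_cut sizes terminal fragments from the first recognition site", {
  reg <- restriction_enzymes()
  expect_equal(first_cut("AAAAGGCCTT", reg$HaeIII), 6L)   # site at index 4, +2
  expect_equal(first_cut("ATATATATAT", reg$HaeIII), NA_integer_)
  expect_equal(first_cut("CCGGAA", reg$MspI), 1L)         # site at 0, +1
  expect_equal(first_cut("AAAAGGCCTT", reg$HaeIII, origin_offset = 20L), 26L)
  # IUPAC site: user-defined enzyme with ambiguity expands to base sets,
  # but N in the read never completes a site
  enz <- restriction_enzyme("toy", "GCNGC", 2L)
  expect_equal(first_cut("TTGCAGCTT", enz), 4L)
  expect_equal(first_cut("TTGCNGCTT", enz), NA_integer_)
})

test_that("first_cut equals the naive per-position scan oracle on random reads", {
  set.seed(606)
  enzymes <- restriction_enzymes()
  seqs <- random_dna(1000, 120)
  for (nm in c("HaeIII", "MspI", "TaqI")) {
    e <- enzymes[[nm]]
    got <- first_cut(seqs, e)
    want <- vapply(seqs, function(s) {
      idx <- oracle_first_site(s, e$recognition)
      if (is.na(idx)) NA_integer_ else idx + e$cut_offset
    }, integer(1), USE.NAMES = FALSE)
    expect_equal(got, want, info = nm)
  }
  # and on an ambiguous site
  toy <- restriction_enzyme("toy", "GGNCC", 3L)
  got <- first_cut(seqs, toy)
  want <- vapply(seqs, function(s) {
    idx <- oracle_first_site(s, "GGNCC")
    if (is.na(idx)) NA_integer_ else idx + 3L
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("digestion aggregates cluster sizes per fragment size and conserves reads", {
  # four clusters all cutting at 219 bp, sizes mirroring a dominant phylotype
  mk_seq <- function() paste0(paste(rep("AT", 108), collapse = ""), "A", "GGCC",
                              strrep("T", 40))
  clusters <- data.frame(centroid_id = sprintf("c%d", 1:4),
                         sequence = rep(mk_seq(), 4),
                         size = c(769L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  clusters$member_ids <- as.list(clusters$centroid_id)
  class(clusters) <- c("seq_clusters", "data.frame")
  dg <- digest_dataset(clusters, enzyme = restriction_enzymes()$HaeIII)
  expect_equal(dg$trfs$size, 219L)
  expect_equal(dg$trfs$count, 772L)
  expect_equal(nrow(dg$contributions), 4L)
  expect_equal(sum(dg$trfs$count) + dg$discarded, sum(clusters$size))

  # empty input and all-site-free input degenerate cleanly
  empty <- digest_dataset(clusters[0, ], enzyme = restriction_enzymes()$HaeIII)
  expect_equal(nrow(empty$trfs), 0L)
  nofree <- clusters
  nofree$sequence <- strrep("AT", 60)
  dg2 <- digest_dataset(nofree, enzyme = restriction_enzymes()$HaeIII)
  expect_equal(nrow(dg2$trfs), 0L)
  expect_equal(dg2$discarded, sum(clusters$size))
})

test_that("appending a site to site-free reads yields a single predictable T-RF", {
  base <- rep(strrep("ACT", 50), 20)  # site-free scaffold
  k <- 99
  seqs <- paste0(substr(base, 1, k), "GGCC", substr(base, k + 1, 150))
  cl <- reads_as_clusters(make_reads(seqs))
  dg <- digest_dataset(cl, enzyme = restriction_enzymes()$HaeIII)
  expect_equal(dg$trfs$size, k + 2L)  # k + cut_offset
  expect_equal(dg$trfs$count, 20L)
})

test_that("build_profile normalizes counts within the size window", {
  trfs <- data.frame(size = c(100L, 200L), count = c(750L, 250L))
  p <- build_profile(trfs, sample_id = "x")
  expect_equal(p$peaks$abundance, c(75, 25))
  expect_equal(p$kind, "digital")

  single <- build_profile(data.frame(size = 120L, count = 7L))
  expect_equal(single$peaks$abundance, 100)

  ranged <- build_profile(data.frame(size = c(60L, 510L), count = c(1L, 1L)))
  expect_equal(ranged$peaks$size, 60L)
  expect_equal(ranged$peaks$abundance, 100)

  expect_error(build_profile(data.frame(size = integer(0), count = integer(0))),
               "empty profile")
})

test_that("error-free synthetic community recovers ground-truth fragment sizes", {
  ref <- make_reference_db(n_taxa = 5, length = 420,
                           site_positions = c(80L, 120L, 160L, 200L, 240L),
                           seed = 9)
  expect_equal(ref$truth$trf_size, c(82L, 122L, 162L, 202L, 242L))
  sim <- simulate_reads(community_spec(ref$db, rep(0.2, 5), read_count = 50,
                                       substitution_rate = 0,
                                       homopolymer_indel_rate = 0, seed = 10))
  cl <- denoise_cluster(sim$reads)
  dg <- digest_dataset(cl, enzyme = restriction_enzymes()$HaeIII)
  expect_setequal(dg$trfs$size, ref$truth$trf_size)
})
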