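# run body with a local RNG seed, restoring global RNG state afterwards
with_local_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  body()
}

#' Generate a synthetic taxonomy-annotated reference database
#'
#' Builds `n_taxa` random reference sequences with rank-complete taxonomy
#' strings and synthetic accessions. Each taxon's first recognition site for
#' the chosen enzyme can be pinned at a given 0-based position, so the true
#' terminal-fragment size of each taxon is known by construction
#' (`position + cut_offset`); accidental earlier site occurrences are
#' mutated away. Deterministic for a fixed seed.
#'
#' @param n_taxa number of reference taxa.
#' @param length reference sequence length in bp.
#' @param enzyme a [restriction_enzyme()] (default HaeIII).
#' @param site_positions optional integer vector (length `n_taxa`) of pinned
#'   0-based first-site positions; default: distinct positions evenly spread
#'   over `[60, 240]` bp, so every fragment terminates well within even the
#'   shortest (300 bp) simulated reads - mirroring real bacterial HaeIII
#'   fingerprints, whose fragments concentrate below 300 bp.
#' @param seed integer RNG seed.
#' @return `list(db, truth)`: `db` a `ref_db` table; `truth` a data frame
#'   with `accession`, `taxonomy`, `site_position` and `trf_size` (true
#'   fragment size at `origin_offset = 0`).
#' @export
make_reference_db <- function(n_taxa = 6L, length = 480L,
                              enzyme = restriction_enzymes()$HaeIII,
                              site_positions = NULL, seed = 1L) {
  site <- enzyme$recognition
  k <- nchar(site)
  if (is.null(site_positions)) {
    lo <- 60L; hi <- min(240L, length - k - 10L)
    if (hi <= lo) stop("reference length too short to place distinct restriction sites")
    site_positions <- as.integer(round(seq(lo, hi, length.out = n_taxa)))
  }
  site_positions <- as.integer(site_positions)
  if (length(site_positions) != n_taxa) stop("need one site position per taxon")
  if (any(site_positions < 0L | site_positions > length - k))
    stop("pinned site position outside the sequence")
  check_nucleotides(site, "recognition site")
  if (grepl("[^ACGT]", site)) stop("pinned layout requires an unambiguous recognition site")

  with_local_seed(seed, function() {
    seqs <- character(n_taxa)
    for (i in seq_len(n_taxa)) {
      s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      pos <- site_positions[i]
      s[(pos + 1L):(pos + k)] <- strsplit(site, "")[[1]]
      seq_str <- paste(s, collapse = "")
      # break any accidental site occurring before the pinned one
      repeat {
        first <- regexpr(site, seq_str, fixed = TRUE)
        if (first == pos + 1L) break
        if (first < 1L || first > pos + 1L)
          stop("failed to pin restriction site for taxon ", i)
        j <- as.integer(first)  # mutate the first base of the stray site
        cur <- substr(seq_str, j, j)
        repl <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
        substr(seq_str, j, j) <- repl
      }
      seqs[i] <- seq_str
    }
    ranks <- sprintf("P:Phylum%02d;C:Class%02d;O:Order%02d;F:Family%02d;G:Genus%02d;S:Genus%02d species%02d",
                     seq_len(n_taxa), seq_len(n_taxa), seq_len(n_taxa),
                     seq_len(n_taxa), seq_len(n_taxa), seq_len(n_taxa), seq_len(n_taxa))
    db <- data.frame(otu_id = as.character(seq_len(n_taxa)),
                     accession = sprintf("SYN%04d", seq_len(n_taxa)),
                     taxonomy = ranks, sequence = seqs, stringsAsFactors = FALSE)
    class(db) <- c("ref_db", "data.frame")
    truth <- data.frame(accession = db$accession, taxonomy = db$taxonomy,
                        site_position = site_positions,
                        trf_size = site_positions + enzyme$cut_offset,
                        stringsAsFactors = FALSE)
    if (anyDuplicated(truth$trf_size))
      stop("requested site layout yields duplicate T-RF sizes")
    list(db = db, truth = truth)
  })
}

#' Specification of a synthetic amplicon community
#'
#' @param db a `ref_db` of source taxa (e.g. from [make_reference_db()]).
#' @param abundances relative abundances, one per taxon, summing to 1.
#' @param read_count number of reads to simulate.
#' @param substitution_rate per-base substitution probability.
#' @param homopolymer_indel_rate per-homopolymer-run (length >= 3)
#'   probability of a +/-1 length error - the dominant 454 error mode.
#' @param length_range read length bounds in bp (reads are 5' prefixes of
#'   the references, as after primer trimming).
#' @param seed integer RNG seed.
#' @return a list of class `community_spec`.
#' @export
community_spec <- function(db, abundances = NULL, read_count = 300L,
                           substitution_rate = 0.005,
                           homopolymer_indel_rate = 0.02,
                           length_range = c(300L, 480L), seed = 1L) {
  n <- nrow(db)
  if (is.null(abundances)) abundances <- rep(1 / n, n)
  stopifnot(length(abundances) == n, all(abundances >= 0),
            abs(sum(abundances) - 1) < 1e-8,
            substitution_rate >= 0, substitution_rate < 1,
            homopolymer_indel_rate >= 0, homopolymer_indel_rate < 1)
  structure(list(db = db, abundances = abundances,
                 read_count = as.integer(read_count),
                 substitution_rate = substitution_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "community_spec")
}

# inject +/-1 errors into homopolymer runs of length >= 3, carrying the
# per-base edited flags through; coordinates follow the returned sequence
perturb_homopolymers <- function(chars, rate, edited = logical(length(chars))) {
  if (rate <= 0 || length(chars) < 3) return(list(chars = chars, edited = edited))
  r <- rle(chars)
  runs <- which(r$lengths >= 3)
  if (!length(runs)) return(list(chars = chars, edited = edited))
  hit <- runs[stats::runif(length(runs)) < rate]
  if (!length(hit)) return(list(chars = chars, edited = edited))
  ends <- cumsum(r$lengths)
  out <- character(0); out_ed <- logical(0)
  prev_end <- 0L
  for (i in seq_along(r$lengths)) {
    run_chars <- chars[(prev_end + 1L):ends[i]]
    run_ed <- edited[(prev_end + 1L):ends[i]]
    if (i %in% hit) {
      if (stats::runif(1) < 0.5 && length(run_chars) > 1L) {
        run_chars <- run_chars[-1L]; run_ed <- run_ed[-1L]  # deletion
        if (length(run_ed)) run_ed[1L] <- TRUE
      } else {
        run_chars <- c(run_chars, run_chars[1L])            # insertion
        run_ed <- c(run_ed, TRUE)
      }
    }
    out <- c(out, run_chars); out_ed <- c(out_ed, run_ed)
    prev_end <- ends[i]
  }
  list(chars = out, edited = out_ed)
}

#' Simulate error-bearing amplicon reads from a known community
#'
#' Draws reads from the reference taxa according to their abundances; each
#' read is a 5' prefix of its source reference (uniform length within
#' `length_range`, capped by the reference length), with per-base
#' substitutions and homopolymer +/-1 indels injected at the specified
#' rates. PHRED qualities are Q40 for clean bases and Q10 for edited ones.
#' Deterministic for a fixed seed.
#'
#' @param spec a [community_spec()].
#' @return `list(reads, truth)`: `reads` a `trf_reads` table; `truth` a data
#'   frame with per-read `id`, source `accession` and `taxonomy`.
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_local_seed(spec$seed, function() {
    n <- spec$read_count
    taxon <- sample.int(nrow(spec$db), n, replace = TRUE, prob = spec$abundances)
    ids <- sprintf("read_%05d", seq_len(n))
    seqs <- character(n); quals <- vector("list", n)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
      ref <- spec$db$sequence[taxon[i]]
      len_choices <- spec$length_range[1]:spec$length_range[2]
      len <- min(nchar(ref), len_choices[sample.int(length(len_choices), 1)])
      chars <- strsplit(substr(ref, 1, len), "")[[1]]
      edited <- logical(len)
      if (spec$substitution_rate > 0) {
        sub_at <- which(stats::runif(len) < spec$substitution_rate)
        for (j in sub_at) {
          chars[j] <- sample(setdiff(bases, chars[j]), 1)
          edited[j] <- TRUE
        }
      }
      hp <- perturb_homopolymers(chars, spec$homopolymer_indel_rate, edited)
      seqs[i] <- paste(hp$chars, collapse = "")
      quals[[i]] <- ifelse(hp$edited, 10L, 40L)
    }
    reads <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
    reads$quality <- quals
    class(reads) <- c("trf_reads", "data.frame")
    truth <- data.frame(id = ids, accession = spec$db$accession[taxon],
                        taxonomy = spec$db$taxonomy[taxon],
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Derive a drifted experimental T-RFLP profile from ground truth
#'
#' Emulates the electropherogram the lab workflow would produce from a known
#' community: the expected digital profile (true fragment size per taxon,
#' abundance-weighted) with every size shifted down by `drift` bp -
#' electrophoresis runs terminal fragments 4-6 bp short of their in-silico
#' size - peaks below the detection floor removed, and abundances
#' renormalized.
#'
#' @param db_truth the `truth` component of [make_reference_db()].
#' @param abundances relative abundances, one per taxon (sum 1).
#' @param drift positive integer bp subtracted from every true size.
#' @param detection_floor percent below which peaks go undetected.
#' @param sample_id sample identifier.
#' @param size_range electropherogram window (peaks shifted below 50 bp are
#'   dropped with a warning).
#' @param path optional CSV path; when given the profile is also written via
#'   [write_profile()].
#' @return a [trflp_profile] with `kind = "experimental"`.
#' @export
derive_etrflp <- function(db_truth, abundances, drift = 5L, detection_floor = 0,
                          sample_id = "synthetic", size_range = c(50L, 500L),
                          path = NULL) {
  stopifnot(length(abundances) == nrow(db_truth), abs(sum(abundances) - 1) < 1e-8)
  pk <- data.frame(size = db_truth$trf_size - as.integer(drift),
                   abundance = 100 * abundances)
  pk <- stats::aggregate(abundance ~ size, data = pk, FUN = sum)
  low <- pk$size < size_range[1] | pk$size > size_range[2]
  if (any(low)) {
    warning(sum(low), " shifted peak(s) outside [", size_range[1], ",",
            size_range[2], "] bp dropped")
    pk <- pk[!low, , drop = FALSE]
  }
  pk <- pk[pk$abundance >= detection_floor, , drop = FALSE]
  if (nrow(pk) == 0L) stop("no detectable peaks after drift and floor")
  prof <- trflp_profile(renormalize_peaks(pk), sample_id = sample_id,
                        kind = "experimental", size_range = size_range)
  if (!is.null(path)) write_profile(prof, path)
  prof
}
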