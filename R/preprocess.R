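#' PHRED score to base-calling error probability
#'
#' @param q integer PHRED score(s), `q >= 0`.
#' @return `10^(-q/10)`, in `(0, 1]`.
#' @examples
#' phred_error_prob(20)  # 0.01
#' @export
phred_error_prob <- function(q) {
  if (any(q < 0)) stop("PHRED score must be non-negative")
  10^(-q / 10)
}

#' Quality-filter configuration
#'
#' Defaults follow common 454 amplicon practice: reads between the minimum
#' amplicon length (300 bp) and the maximum amplicon length (500 bp), with a
#' mean PHRED quality of at least 20 (1% expected error per base).
#'
#' @param min_phred minimum mean PHRED score (0-60).
#' @param min_len,max_len inclusive read length bounds in bp.
#' @return a list of class `quality_filter_config`.
#' @export
quality_filter_config <- function(min_phred = 20, min_len = 300L, max_len = 500L) {
  stopifnot(min_phred >= 0, min_phred <= 60, min_len > 0, min_len <= max_len)
  structure(list(min_phred = min_phred, min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "quality_filter_config")
}

iupac_sets <- c(A = "A", C = "C", G = "G", T = "T",
                M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
                V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT")

#' Trim amplification primers from reads
#'
#' The forward primer is matched at the read start with IUPAC ambiguity codes
#' expanded (e.g. `M` matches `A` or `C`), allowing up to `max_mismatch`
#' mismatches; reads without a forward-primer match are rejected. If a
#' reverse primer is given, its reverse complement is searched near the 3'
#' end and trimmed when present (its absence is not a rejection: shorter
#' reads may simply not reach it).
#'
#' @param reads a `trf_reads` table.
#' @param fwd forward primer, 5'->3' (IUPAC allowed), e.g. the bacterial 8f
#'   primer `"AGAGTTTGATCMTGGCTCAG"`.
#' @param rev optional reverse primer, 5'->3' on the opposite strand, e.g.
#'   518r `"ATTACCGCGGCTGCTGG"`.
#' @param max_mismatch mismatches tolerated in each primer match.
#' @return `list(reads = trimmed kept reads, rejected = data.frame(id, reason))`.
#' @export
trim_primers <- function(reads, fwd, rev = NULL, max_mismatch = 1L) {
  stopifnot(is.data.frame(reads), nzchar(fwd))
  fwd <- toupper(fwd)
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  # per-read match at position 1 with ambiguity codes expanded in the primer only
  hit <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (length(s) < nchar(fwd)) return(FALSE)
    Biostrings::isMatchingStartingAt(Biostrings::DNAString(fwd), s,
                                     starting.at = 1L,
                                     max.mismatch = max_mismatch,
                                     fixed = "subject")
  }, logical(1))
  kept <- reads[hit, , drop = FALSE]
  rejected <- data.frame(id = reads$id[!hit],
                         reason = rep("fwd_primer_absent", sum(!hit)))
  if (nrow(kept)) {
    nf <- nchar(fwd)
    kept$sequence <- substring(kept$sequence, nf + 1L)
    kept$quality <- lapply(kept$quality, function(q) if (is.null(q)) NULL else q[-seq_len(nf)])
    if (!is.null(rev) && nzchar(rev)) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(rev))))
      for (i in seq_len(nrow(kept))) {
        s <- Biostrings::DNAString(kept$sequence[i])
        m <- Biostrings::matchPattern(rc, s, max.mismatch = max_mismatch, fixed = "subject")
        if (length(m)) {
          cut <- Biostrings::start(m)[length(m)] - 1L  # rightmost occurrence
          kept$sequence[i] <- substr(kept$sequence[i], 1L, cut)
          if (!is.null(kept$quality[[i]])) kept$quality[[i]] <- kept$quality[[i]][seq_len(cut)]
        }
      }
    }
    drop_empty <- nchar(kept$sequence) == 0L
    if (any(drop_empty)) {
      rejected <- rbind(rejected, data.frame(id = kept$id[drop_empty],
                                             reason = "empty_after_trim"))
      kept <- kept[!drop_empty, , drop = FALSE]
    }
  }
  rownames(kept) <- NULL
  class(kept) <- c("trf_reads", "data.frame")
  list(reads = kept, rejected = rejected)
}

#' Filter reads on length and mean quality
#'
#' A read is kept when `min_len <= length <= max_len` and (when per-base
#' qualities are present) its mean PHRED score is at least `min_phred`.
#' Reads without qualities are judged on length alone and counted in the
#' stats.
#'
#' @param reads a `trf_reads` table.
#' @param cfg a [quality_filter_config()].
#' @return `list(reads = kept, stats = list(input, kept, rejected_short,
#'   rejected_long, rejected_quality, no_quality))`.
#' @export
quality_filter <- function(reads, cfg = quality_filter_config()) {
  stopifnot(inherits(cfg, "quality_filter_config"))
  len <- nchar(reads$sequence)
  has_q <- !vapply(reads$quality, is.null, logical(1))
  meanq <- rep(NA_real_, nrow(reads))
  meanq[has_q] <- vapply(reads$quality[has_q], mean, numeric(1))
  too_short <- len < cfg$min_len
  too_long <- len > cfg$max_len
  low_q <- has_q & !too_short & !too_long & meanq < cfg$min_phred
  keep <- !too_short & !too_long & !low_q
  stats <- list(input = nrow(reads), kept = sum(keep),
                rejected_short = sum(too_short), rejected_long = sum(too_long),
                rejected_quality = sum(low_q), no_quality = sum(!has_q))
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("trf_reads", "data.frame")
  list(reads = kept, stats = stats)
}

# ends-free pairwise identity: matches / alignment columns, with
# match +1, mismatch -1, linear gap -1 so internal indels are penalised
pairwise_identity <- function(candidates, subject) {
  mat <- identity_submat()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(candidates), subject,
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  n_cols <- Biostrings::nchar(aln)
  ifelse(n_cols == 0L, 0, Biostrings::nmatch(aln) / n_cols)
}

submat_cache <- new.env(parent = emptyenv())

identity_submat <- function() {
  if (is.null(submat_cache$ident)) {
    letters <- names(iupac_sets)
    m <- matrix(-1, length(letters), length(letters), dimnames = list(letters, letters))
    diag(m)[1:4] <- 1  # only unambiguous equal bases count as matches
    submat_cache$ident <- m
  }
  submat_cache$ident
}

#' Denoise reads by greedy identity clustering
#'
#' Collapses sequencing-error variants into abundance-weighted centroid
#' sequences, UCLUST-style: reads are dereplicated into unique sequences,
#' ordered by descending duplicate count (ties broken lexicographically by
#' sequence so the procedure is deterministic without seeds), then processed
#' greedily - a sequence joins the first existing centroid with pairwise
#' identity at or above the threshold, otherwise it founds a new cluster.
#' Identity is matches over alignment columns of an ends-free alignment
#' (match +1, mismatch -1, gap -1). Singletons are retained as size-1
#' clusters, so cluster sizes always sum to the number of input reads.
#'
#' After membership is fixed, each cluster's representative sequence is
#' selected among its members: highest within-cluster duplicate count, ties
#' broken by highest mean base quality, then lexicographically. Choosing the
#' cleanest member (rather than the greedy founder) keeps a founder's
#' sequencing errors - in particular indels upstream of a restriction site -
#' from being attributed to the entire cluster.
#'
#' @param reads a `trf_reads` table (already quality-filtered).
#' @param identity clustering identity threshold in `(0, 1]` (default 0.97,
#'   the conventional OTU radius).
#' @param seed_order `"abundance"` (dereplicate, then descending count) or
#'   `"input"` (first-come order, no dereplication reordering).
#' @return A data frame of class `seq_clusters` with columns `centroid_id`,
#'   `sequence`, `size` (member read count) and `member_ids` (list column).
#' @export
denoise_cluster <- function(reads, identity = 0.97, seed_order = c("abundance", "input")) {
  seed_order <- match.arg(seed_order)
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  if (nrow(reads) == 0L)
    return(empty_clusters())

  ids_by_seq <- split(reads$id, reads$sequence)
  uniq <- data.frame(sequence = names(ids_by_seq), stringsAsFactors = FALSE)
  uniq$count <- lengths(ids_by_seq)
  uniq$members <- unname(ids_by_seq)
  if (seed_order == "abundance") {
    uniq <- uniq[order(-uniq$count, uniq$sequence), , drop = FALSE]
  } else {
    first_pos <- vapply(uniq$members, function(m) match(m[1], reads$id), integer(1))
    uniq <- uniq[order(first_pos), , drop = FALSE]
  }

  # round-based greedy assignment, equivalent to incremental first-fit:
  # the next centroid is always the first still-unassigned sequence, and a
  # sequence joins the earliest-founded centroid reaching the threshold.
  # Each round scores all remaining sequences against one centroid in a
  # single vectorised alignment call.
  cent_seq <- character(0)
  cent_members <- list()
  remaining <- seq_len(nrow(uniq))
  while (length(remaining)) {
    f <- remaining[1]
    cent_seq <- c(cent_seq, uniq$sequence[f])
    members <- uniq$members[[f]]
    remaining <- remaining[-1]
    if (length(remaining)) {
      idents <- pairwise_identity(uniq$sequence[remaining], uniq$sequence[f])
      absorb <- idents >= identity
      if (any(absorb)) {
        members <- c(members, unlist(uniq$members[remaining[absorb]], use.names = FALSE))
        remaining <- remaining[!absorb]
      }
    }
    cent_members[[length(cent_seq)]] <- members
  }

  # representative selection within each cluster: highest duplicate count,
  # then highest mean base quality, then lexicographically smallest sequence.
  # The founder anchors assignment; the representative carried forward to
  # mapping/digestion is the cluster's cleanest member, so a sequencing
  # error in the founder does not propagate to the whole cluster's fragment.
  rep_idx <- vapply(cent_members, function(members) {
    ri <- match(members, reads$id)
    seqs <- reads$sequence[ri]
    dup <- as.integer(table(seqs)[seqs])
    meanq <- vapply(reads$quality[ri], function(q)
      if (is.null(q)) -1 else mean(q), numeric(1))
    ri[order(-dup, -meanq, seqs)[1]]
  }, integer(1))
  out <- data.frame(centroid_id = reads$id[rep_idx],
                    sequence = reads$sequence[rep_idx],
                    size = lengths(cent_members),
                    stringsAsFactors = FALSE)
  out$member_ids <- cent_members
  rownames(out) <- NULL
  class(out) <- c("seq_clusters", "data.frame")
  out
}

empty_clusters <- function() {
  out <- data.frame(centroid_id = character(0), sequence = character(0),
                    size = integer(0), stringsAsFactors = FALSE)
  out$member_ids <- list()
  class(out) <- c("seq_clusters", "data.frame")
  out
}

#' Treat each read as its own cluster (no denoising)
#'
#' Used by the "raw" and "filtered" processing procedures, where digestion
#' operates on every read individually instead of on cluster centroids.
#'
#' @param reads a `trf_reads` table.
#' @return a `seq_clusters` table of size-1 clusters.
#' @export
reads_as_clusters <- function(reads) {
  if (nrow(reads) == 0L) return(empty_clusters())
  out <- data.frame(centroid_id = reads$id, sequence = reads$sequence,
                    size = 1L, stringsAsFactors = FALSE)
  out$member_ids <- as.list(reads$id)
  rownames(out) <- NULL
  class(out) <- c("seq_clusters", "data.frame")
  out
}
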