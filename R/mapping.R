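#' Alignment scoring scheme
#'
#' Affine-gap local alignment parameters. The defaults (+1 match, 3
#' mismatch, 5 gap open, 2 gap extend) mirror BWA-SW's, under which a
#' perfect full-length match of an `L`-bp read scores `L` - e.g. around 450
#' for the longest 454 amplicon reads - and the score normalized by read
#' length is bounded by 1.
#'
#' @param match positive match reward.
#' @param mismatch,gap_open,gap_extend non-negative penalties (entered as
#'   positive numbers).
#' @return a list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = 3L, gap_open = 5L, gap_extend = 2L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

sw_submat <- function(scheme) {
  key <- paste0("sw_", scheme$match, "_", scheme$mismatch)
  if (is.null(submat_cache[[key]])) {
    letters <- names(iupac_sets)
    m <- matrix(-scheme$mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m)[1:4] <- scheme$match  # ambiguity codes never reward a match
    submat_cache[[key]] <- m
  }
  submat_cache[[key]]
}

check_nucleotides <- function(x, what) {
  bad <- grepl("[^ACGTMRWSYKVHDBN]", x)
  if (any(bad)) stop("non-IUPAC characters in ", what)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment of two nucleotide strings under affine gap costs
#' (a gap of length k costs `gap_open + k * gap_extend`). An all-mismatch
#' pair scores 0 (the empty local alignment).
#'
#' @param query,reference non-empty nucleotide strings (IUPAC letters;
#'   ambiguity codes score as mismatches).
#' @param scheme a [scoring_scheme()].
#' @return `list(score, query_span, ref_span)` where the spans are half-open
#'   `[start, end)` 0-based intervals (both `c(0, 0)` for a score of 0).
#' @examples
#' sw_align("ACGTACGTAC", "ACGTTCGTAC")$score  # 6: 9 matches - 1 mismatch
#' @export
sw_align <- function(query, reference, scheme = scoring_scheme()) {
  query <- toupper(query); reference <- toupper(reference)
  if (!nzchar(query) || !nzchar(reference)) stop("sequences must be non-empty")
  check_nucleotides(c(query, reference), "sw_align input")
  aln <- Biostrings::pairwiseAlignment(
    query, reference, type = "local",
    substitutionMatrix = sw_submat(scheme),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- max(0, Biostrings::score(aln))
  if (sc == 0)
    return(list(score = 0, query_span = c(0L, 0L), ref_span = c(0L, 0L)))
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  list(score = sc,
       query_span = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
       ref_span = c(Biostrings::start(s) - 1L, Biostrings::end(s)))
}

# score one query (both orientations) against every reference; vectorised
# over the database. Returns list(scores, strand) of the better orientation.
score_against_db <- function(query, db_set, scheme) {
  mat <- sw_submat(scheme)
  fwd <- Biostrings::pairwiseAlignment(
    db_set, query, type = "local", substitutionMatrix = mat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  rev <- Biostrings::pairwiseAlignment(
    db_set, rc, type = "local", substitutionMatrix = mat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  fwd <- pmax(0, fwd); rev <- pmax(0, rev)
  strand <- ifelse(rev > fwd, "-", "+")
  list(scores = pmax(fwd, rev), strand = strand)
}

#' Map cluster centroids against a reference database
#'
#' Exhaustive Smith-Waterman search: every centroid is aligned against every
#' reference (both orientations; the better one wins) and the single best
#' hit is retained. Clusters whose best score falls below `min_score` are
#' routed to the unmapped list and leave the pipeline. Score ties between
#' references are resolved toward the earlier database record (and logged).
#'
#' @param clusters a `seq_clusters` table.
#' @param db a `ref_db` reference table ([read_reference_db()]).
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum SW score to keep a hit (default 150; typical
#'   working range 100-250, settable to 0 to disable filtering).
#' @return `list(hits, unmapped, stats)`: `hits` is a data frame (class
#'   `mapping_hits`) with `query_id`, `cluster_size`, `accession`, `otu_id`,
#'   `taxonomy`, `sw_score`, `norm_score` (score / query length) and
#'   `strand`; `unmapped` the rejected query ids; `stats` totals and median
#'   absolute/normalized scores of the mapped set.
#' @export
map_clusters <- function(clusters, db, scheme = scoring_scheme(), min_score = 150) {
  stopifnot(is.data.frame(db), nrow(db) > 0)
  n <- nrow(clusters)
  hits <- data.frame(query_id = character(0), cluster_size = integer(0),
                     accession = character(0), otu_id = character(0),
                     taxonomy = character(0), sw_score = numeric(0),
                     norm_score = numeric(0), strand = character(0),
                     stringsAsFactors = FALSE)
  unmapped <- character(0)
  if (n > 0) {
    check_nucleotides(clusters$sequence, "cluster centroids")
    db_set <- Biostrings::DNAStringSet(db$sequence)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      res <- score_against_db(clusters$sequence[i], db_set, scheme)
      best <- which.max(res$scores)  # earliest database record on ties
      if (sum(res$scores == res$scores[best]) > 1)
        message("mapping tie for ", clusters$centroid_id[i],
                " resolved toward earlier reference ", db$accession[best])
      if (res$scores[best] < min_score) {
        unmapped <- c(unmapped, clusters$centroid_id[i])
      } else {
        rows[[i]] <- data.frame(
          query_id = clusters$centroid_id[i], cluster_size = clusters$size[i],
          accession = db$accession[best], otu_id = db$otu_id[best],
          taxonomy = db$taxonomy[best], sw_score = res$scores[best],
          norm_score = res$scores[best] / nchar(clusters$sequence[i]),
          strand = res$strand[best], stringsAsFactors = FALSE)
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) hits <- do.call(rbind, rows)
  }
  rownames(hits) <- NULL
  class(hits) <- c("mapping_hits", "data.frame")
  stats <- list(queries = n, mapped = nrow(hits), unmapped = length(unmapped),
                reads_in = sum(clusters$size), reads_mapped = sum(hits$cluster_size),
                median_sw = if (nrow(hits)) stats::median(hits$sw_score) else NA_real_,
                median_norm = if (nrow(hits)) stats::median(hits$norm_score) else NA_real_)
  list(hits = hits, unmapped = unmapped, stats = stats)
}

#' Write mapping statistics and the unmapped-read list
#'
#' @param mapping result of [map_clusters()].
#' @param stats_path CSV path for the per-sample mapping statistics.
#' @param unmapped_path text path, one unmapped query id per line.
#' @param sample_id sample identifier written into the stats row.
#' @return invisibly, the stats data frame.
#' @export
write_mapping_report <- function(mapping, stats_path, unmapped_path,
                                 sample_id = "sample") {
  s <- mapping$stats
  df <- data.frame(sample = sample_id, queries = s$queries, mapped = s$mapped,
                   unmapped = s$unmapped, reads_in = s$reads_in,
                   reads_mapped = s$reads_mapped,
                   median_sw = s$median_sw, median_norm_sw = round(s$median_norm, 3))
  utils::write.csv(df, stats_path, row.names = FALSE, quote = FALSE)
  writeLines(mapping$unmapped, unmapped_path)
  invisible(df)
}
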