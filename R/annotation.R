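#' Annotate digital T-RFs with ranked phylotype contributions
#'
#' Produces the peak-annotation table: for each digital T-RF, the
#' contributing phylotypes grouped by reference accession, with read counts,
#' relative contributions (percent of the T-RF's reads, 1 decimal), the
#' representative SW scores (those of the largest contributing cluster),
#' accession and OTU id, sorted by descending count. When a drift lag is
#' known the shifted size is reported, and matched experimental T-RF sizes
#' are attached; without eT-RFLP data both columns stay `NA`.
#'
#' @param digest a `trf_digest` from [digest_dataset()] (annotated, i.e.
#'   produced with mapping hits).
#' @param lag optional drift lag in bp (shifted size = size + lag).
#' @param matches optional result of [match_peaks()] against the shifted
#'   profile.
#' @return A data frame of class `trf_annotation`, one row per (T-RF,
#'   phylotype): `dtrf_size`, `shifted_size`, `etrf_size`, `taxonomy`,
#'   `count`, `contribution`, `sw_score`, `norm_score`, `accession`,
#'   `otu_id`.
#' @export
annotate_trfs <- function(digest, lag = NULL, matches = NULL) {
  stopifnot(inherits(digest, "trf_digest"))
  contrib <- digest$contributions
  if (nrow(contrib) == 0L) {
    out <- data.frame(dtrf_size = integer(0), shifted_size = integer(0),
                      etrf_size = integer(0), taxonomy = character(0),
                      count = integer(0), contribution = numeric(0),
                      sw_score = numeric(0), norm_score = numeric(0),
                      accession = character(0), otu_id = character(0))
    class(out) <- c("trf_annotation", "data.frame")
    return(out)
  }
  key <- paste(contrib$size, contrib$accession, contrib$taxonomy, sep = "\r")
  grp <- split(contrib, key)
  rows <- lapply(grp, function(g) {
    rep_row <- g[order(-g$count, -g$sw_score), , drop = FALSE][1, ]
    data.frame(dtrf_size = g$size[1], taxonomy = g$taxonomy[1],
               count = sum(g$count), sw_score = rep_row$sw_score,
               norm_score = round1(rep_row$norm_score, 3L),
               accession = g$accession[1], otu_id = g$otu_id[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  totals <- tapply(out$count, out$dtrf_size, sum)
  out$contribution <- round1(100 * out$count / as.numeric(totals[as.character(out$dtrf_size)]))
  out$shifted_size <- if (!is.null(lag)) out$dtrf_size + as.integer(lag) else NA_integer_
  out$etrf_size <- NA_integer_
  if (!is.null(matches) && !is.null(lag) && nrow(matches$matches)) {
    mi <- match(out$shifted_size, matches$matches$shifted_dtrf_size)
    out$etrf_size <- matches$matches$etrf_size[mi]
  }
  out <- out[order(out$dtrf_size, -out$count, out$accession),
             c("dtrf_size", "shifted_size", "etrf_size", "taxonomy", "count",
               "contribution", "sw_score", "norm_score", "accession", "otu_id")]
  rownames(out) <- NULL
  class(out) <- c("trf_annotation", "data.frame")
  out
}

#' Relative contributions from read counts
#'
#' Helper for the contribution arithmetic of the peak-annotation table:
#' percent of the T-RF total, rounded half-up to 1 decimal.
#'
#' @param counts integer read counts of the phylotypes contributing to one
#'   T-RF.
#' @param total T-RF total (defaults to `sum(counts)`).
#' @return numeric vector of percentages.
#' @examples
#' trf_contributions(c(769, 1, 1, 1))  # 99.6 0.1 0.1 0.1
#' @export
trf_contributions <- function(counts, total = sum(counts)) {
  round1(100 * counts / total)
}

#' T-RF diversity table for one phylogenetic description
#'
#' Lists every digital T-RF whose taxonomy matches the query (fixed,
#' case-insensitive substring), one row per (T-RF, accession), sorted by
#' size, flagging the predominant row (highest count). Sequencing indels
#' upstream of the first restriction site scatter one phylotype across
#' several T-RF sizes; this table exposes that spread.
#'
#' @param annotations a `trf_annotation` table.
#' @param taxon taxonomy query string, e.g. `"Dehalococcoides"`.
#' @return subset of `annotations` with an added logical `predominant`
#'   column; empty when the taxon is absent.
#' @export
taxon_trf_table <- function(annotations, taxon) {
  hit <- grepl(taxon, annotations$taxonomy, ignore.case = TRUE, fixed = FALSE)
  out <- annotations[hit, , drop = FALSE]
  out <- out[order(out$dtrf_size), , drop = FALSE]
  out$predominant <- if (nrow(out)) out$count == max(out$count) else logical(0)
  rownames(out) <- NULL
  out
}

#' Write the peak-annotation CSV
#'
#' @param annotations a `trf_annotation` table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
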