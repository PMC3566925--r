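#' Define a restriction enzyme
#'
#' An enzyme is its recognition site (IUPAC letters allowed) plus the 0-based
#' cut offset within the site on the labeled strand: a terminal fragment ends
#' `cut_offset` bases into the first site occurrence.
#'
#' @param name enzyme name.
#' @param recognition recognition site, length >= 4.
#' @param cut_offset integer in `[0, nchar(recognition)]`.
#' @return a list of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("HaeIII", "GGCC", 2L)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4) stop("recognition site must be at least 4 bp")
  check_nucleotides(recognition, "recognition site")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset outside recognition site")
  structure(list(name = name, recognition = recognition, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' Built-in restriction enzyme registry
#'
#' The six 4-cutters commonly used in bacterial community T-RFLP, with
#' REBASE recognition sites and cut offsets: HaeIII (GG^CC), AluI (AG^CT),
#' MspI (C^CGG), HhaI (GCG^C), RsaI (GT^AC) and TaqI (T^CGA).
#'
#' @return named list of [restriction_enzyme()] objects.
#' @export
restriction_enzymes <- function() {
  list(
    HaeIII = restriction_enzyme("HaeIII", "GGCC", 2L),
    AluI   = restriction_enzyme("AluI",   "AGCT", 2L),
    MspI   = restriction_enzyme("MspI",   "CCGG", 1L),
    HhaI   = restriction_enzyme("HhaI",   "GCGC", 3L),
    RsaI   = restriction_enzyme("RsaI",   "GTAC", 2L),
    TaqI   = restriction_enzyme("TaqI",   "TCGA", 1L))
}

#' Look up an enzyme by name
#'
#' @param name registry name (case-insensitive), e.g. `"HaeIII"`.
#' @return a [restriction_enzyme()].
#' @export
get_enzyme <- function(name) {
  reg <- restriction_enzymes()
  i <- match(tolower(name), tolower(names(reg)))
  if (is.na(i)) stop("unknown enzyme '", name, "'; registry: ",
                     paste(names(reg), collapse = ", "))
  reg[[i]]
}

# recognition site -> regex with IUPAC expansion; expansions cover only
# A/C/G/T, so an N in the read never completes a site
site_regex <- function(recognition) {
  chars <- strsplit(recognition, "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- iupac_sets[[ch]]
    if (nchar(set) == 1) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

#' Terminal fragment size from the first restriction site
#'
#' Scans the sequence 5'->3' from the labeled-primer end for the first
#' occurrence of the recognition site; the terminal-restriction fragment
#' (T-RF) size is the 0-based site index plus the cut offset plus
#' `origin_offset` (use `origin_offset` to re-add trimmed primer bases when
#' fragment sizes should be counted from the primer 5' end).
#'
#' @param sequence nucleotide string(s), vectorised.
#' @param enzyme a [restriction_enzyme()].
#' @param origin_offset integer added to every fragment size (default 0).
#' @return integer vector of T-RF sizes in bp; `NA` where the sequence
#'   carries no site (such reads are discarded from digital profiles).
#' @examples
#' first_cut("AAAAGGCCTT", restriction_enzymes()$HaeIII)  # 6
#' @export
first_cut <- function(sequence, enzyme, origin_offset = 0L) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  pos <- regexpr(site_regex(enzyme$recognition), toupper(sequence))
  size <- ifelse(pos > 0, (as.integer(pos) - 1L) + enzyme$cut_offset + as.integer(origin_offset),
                 NA_integer_)
  as.integer(size)
}

#' Digest a dataset in silico into digital T-RFs
#'
#' Each cluster centroid is digested with the enzyme; centroids with no
#' recognition site are discarded (and counted). Fragments are grouped by
#' integer size; each digital T-RF aggregates its contributing clusters
#' weighted by cluster size (centroid inflation). When mapping hits are
#' supplied, only mapped clusters participate and each contribution carries
#' its best-hit taxonomy and scores; without hits (raw/filtered procedures)
#' all clusters participate, unannotated.
#'
#' @param clusters a `seq_clusters` table.
#' @param hits optional `mapping_hits` from [map_clusters()].
#' @param enzyme a [restriction_enzyme()].
#' @param origin_offset see [first_cut()].
#' @return A list of class `trf_digest`: `trfs` (data frame `size`, `count`),
#'   `contributions` (data frame `size`, `query_id`, `count`, `accession`,
#'   `otu_id`, `taxonomy`, `sw_score`, `norm_score`), `discarded` (reads in
#'   site-free clusters), `enzyme`, `origin_offset`.
#' @export
digest_dataset <- function(clusters, hits = NULL, enzyme = restriction_enzymes()$HaeIII,
                           origin_offset = 0L) {
  if (!is.null(hits)) {
    keep <- match(hits$query_id, clusters$centroid_id)
    part <- clusters[keep, , drop = FALSE]
    ann <- hits
  } else {
    part <- clusters
    n <- nrow(clusters)
    ann <- data.frame(query_id = clusters$centroid_id,
                      accession = rep(NA_character_, n),
                      otu_id = rep(NA_character_, n),
                      taxonomy = rep(NA_character_, n),
                      sw_score = rep(NA_real_, n),
                      norm_score = rep(NA_real_, n), stringsAsFactors = FALSE)
  }
  empty_digest <- function(discarded) {
    structure(list(trfs = data.frame(size = integer(0), count = integer(0)),
                   contributions = data.frame(),
                   discarded = discarded, enzyme = enzyme,
                   origin_offset = as.integer(origin_offset)),
              class = "trf_digest")
  }
  if (nrow(part) == 0L) return(empty_digest(0L))
  sizes <- first_cut(part$sequence, enzyme, origin_offset)
  cut_ok <- !is.na(sizes)
  discarded <- sum(part$size[!cut_ok])
  if (!any(cut_ok)) return(empty_digest(discarded))
  contrib <- data.frame(size = sizes[cut_ok],
                        query_id = part$centroid_id[cut_ok],
                        count = part$size[cut_ok], stringsAsFactors = FALSE)
  ai <- match(contrib$query_id, ann$query_id)
  contrib$accession <- ann$accession[ai]
  contrib$otu_id <- ann$otu_id[ai]
  contrib$taxonomy <- ann$taxonomy[ai]
  contrib$sw_score <- ann$sw_score[ai]
  contrib$norm_score <- ann$norm_score[ai]
  contrib <- contrib[order(contrib$size, -contrib$count, contrib$query_id), , drop = FALSE]
  rownames(contrib) <- NULL
  trfs <- stats::aggregate(count ~ size, data = contrib, FUN = sum)
  trfs <- trfs[order(trfs$size), , drop = FALSE]
  rownames(trfs) <- NULL
  structure(list(trfs = trfs, contributions = contrib, discarded = discarded,
                 enzyme = enzyme, origin_offset = as.integer(origin_offset)),
            class = "trf_digest")
}

#' Build a digital T-RFLP profile from digested fragments
#'
#' Restricts T-RFs to `size_range` (for comparison with electropherogram
#' profiles, `[50, 500]`; use a wider range such as `c(1, 500)` for the raw
#' profile that keeps sub-50 bp fragments) and converts read counts into
#' relative abundances summing to 100.
#'
#' @param digest a `trf_digest` from [digest_dataset()], or a data frame with
#'   columns `size` and `count`.
#' @param sample_id sample identifier.
#' @param size_range inclusive bounds in bp.
#' @return a [trflp_profile] with `kind = "digital"`.
#' @export
build_profile <- function(digest, sample_id = "sample", size_range = c(50L, 500L)) {
  trfs <- if (inherits(digest, "trf_digest")) digest$trfs else digest
  trfs <- trfs[trfs$size >= size_range[1] & trfs$size <= size_range[2], , drop = FALSE]
  if (nrow(trfs) == 0L || sum(trfs$count) == 0)
    stop("empty profile: no T-RFs within [", size_range[1], ",", size_range[2], "] bp")
  peaks <- data.frame(size = trfs$size, abundance = 100 * trfs$count / sum(trfs$count))
  trflp_profile(peaks, sample_id = sample_id, kind = "digital", size_range = size_range)
}
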