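#' Richness and Shannon diversity of a fingerprint
#'
#' Richness is the number of T-RFs with abundance above `min_abundance`
#' (default 0: every detected peak counts). Shannon's H' is `-sum(p ln p)`
#' over the relative abundances, in natural-log units (ecology convention),
#' so H' is at most `ln(richness)` and 0 for a single peak.
#'
#' @param profile a [trflp_profile].
#' @param min_abundance abundance floor in percent below which peaks are
#'   ignored.
#' @return `list(richness, shannon)` of class `profile_indices`.
#' @examples
#' p <- trflp_profile(data.frame(size = 100:109, abundance = rep(10, 10)))
#' profile_indices(p)  # richness 10, H' = ln 10
#' @export
profile_indices <- function(profile, min_abundance = 0) {
  stopifnot(inherits(profile, "trflp_profile"))
  ab <- profile$peaks$abundance
  ab <- ab[ab > min_abundance]
  if (!length(ab)) stop("empty profile: no peaks above the abundance floor")
  p <- ab / sum(ab)
  structure(list(richness = length(ab), shannon = -sum(p * log(p))),
            class = "profile_indices")
}

#' @export
print.profile_indices <- function(x, ...) {
  cat(sprintf("richness %d, Shannon H' %.4f\n", x$richness, x$shannon))
  invisible(x)
}

#' T-RF density report per 50-bp class
#'
#' Counts distinct T-RFs per size class over `[0, 500]` - classes are
#' half-open `[0,50), [50,100), ...` except the final one, which includes
#' 500 - together with the running cumulative curve (whose last value equals
#' the richness) and the profile's diversity indices.
#'
#' @param profile a [trflp_profile].
#' @param enzyme_name optional enzyme label carried into the report.
#' @param class_width class width in bp.
#' @param max_size upper end of the binned domain.
#' @return A list of class `density_report`: `enzyme`, `classes` (data frame
#'   `lower`, `upper`, `count`, `cumulative`), `indices`.
#' @export
density_report <- function(profile, enzyme_name = NULL, class_width = 50L,
                           max_size = 500L) {
  stopifnot(inherits(profile, "trflp_profile"))
  lower <- seq(0L, max_size - class_width, by = class_width)
  upper <- lower + class_width
  sizes <- profile$peaks$size[profile$peaks$abundance > 0]
  cls <- pmin(sizes %/% class_width, length(lower) - 1L)  # final class includes max_size
  count <- tabulate(cls + 1L, nbins = length(lower))
  classes <- data.frame(lower = lower, upper = upper, count = count,
                        cumulative = cumsum(count))
  structure(list(enzyme = enzyme_name, classes = classes,
                 indices = profile_indices(profile)),
            class = "density_report")
}

#' Screen restriction enzymes on a processed dataset
#'
#' Digests the same clusters (optionally restricted to mapped ones) with
#' each enzyme in turn and reports, per enzyme, the digital profile, its
#' density report, and a ranking table by richness and Shannon H' - the
#' practical criteria for choosing the fingerprinting enzyme for a new
#' system. Requires no eT-RFLP input; profiles keep sub-50 bp fragments.
#'
#' @param clusters a `seq_clusters` table.
#' @param hits optional `mapping_hits`; when given, only mapped clusters are
#'   digested.
#' @param enzymes list of [restriction_enzyme()] objects (default: the full
#'   built-in registry).
#' @param sample_id sample identifier.
#' @param size_range profile window in bp; the default keeps all fragments
#'   up to 500 bp.
#' @return A list of class `enzyme_screen`: `reports` (named list of
#'   `density_report`s), `profiles` (named list of profiles, `NULL` where an
#'   enzyme cut nothing), `ranking` (data frame sorted by richness then H').
#' @export
screen_enzymes <- function(clusters, hits = NULL, enzymes = restriction_enzymes(),
                           sample_id = "sample", size_range = c(1L, 500L)) {
  if (!length(enzymes)) stop("empty enzyme list")
  if (is.null(names(enzymes)))
    names(enzymes) <- vapply(enzymes, function(e) e$name, character(1))
  reports <- list(); profiles <- list()
  rows <- list()
  for (nm in names(enzymes)) {
    dg <- digest_dataset(clusters, hits = hits, enzyme = enzymes[[nm]])
    if (nrow(dg$trfs) == 0L ||
        !any(dg$trfs$size >= size_range[1] & dg$trfs$size <= size_range[2])) {
      profiles[nm] <- list(NULL)
      reports[nm] <- list(NULL)
      rows[[nm]] <- data.frame(enzyme = nm, richness = 0L, shannon = NA_real_,
                               reads_digested = sum(dg$trfs$count),
                               reads_discarded = dg$discarded)
      next
    }
    prof <- build_profile(dg, sample_id = sample_id, size_range = size_range)
    profiles[[nm]] <- prof
    reports[[nm]] <- density_report(prof, enzyme_name = nm)
    idx <- reports[[nm]]$indices
    rows[[nm]] <- data.frame(enzyme = nm, richness = idx$richness,
                             shannon = idx$shannon,
                             reads_digested = sum(dg$trfs$count),
                             reads_discarded = dg$discarded)
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$richness, -ranking$shannon), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(reports = reports, profiles = profiles, ranking = ranking),
            class = "enzyme_screen")
}
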