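#' T-RFLP fingerprint profile
#'
#' A T-RFLP profile is a community fingerprint: a set of terminal-restriction
#' fragments (T-RFs), each a peak at an integer fragment size in base pairs
#' with a relative abundance in percent. Profiles are either `"experimental"`
#' (from a capillary-electrophoresis electropherogram) or `"digital"`
#' (computed in silico from sequencing reads).
#'
#' Invariants enforced at construction: sizes are unique integers in strictly
#' increasing order and within `size_range`; abundances are non-negative and
#' sum to 100 (within 1e-6).
#'
#' @param peaks data frame with columns `size` (integer bp) and `abundance`
#'   (percent). Rows are reordered by size.
#' @param sample_id character scalar identifying the sample.
#' @param kind `"experimental"` or `"digital"`.
#' @param size_range length-2 integer vector, inclusive bounds in bp.
#' @return An object of class `trflp_profile`: a list with elements
#'   `sample_id`, `kind`, `peaks` and `size_range`.
#' @examples
#' trflp_profile(data.frame(size = c(100L, 200L), abundance = c(60, 40)),
#'               sample_id = "S1", kind = "digital")
#' @export
trflp_profile <- function(peaks, sample_id = "sample", kind = c("digital", "experimental"),
                          size_range = c(50L, 500L)) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(peaks), all(c("size", "abundance") %in% names(peaks)))
  peaks <- data.frame(size = as.integer(peaks$size), abundance = as.numeric(peaks$abundance))
  if (nrow(peaks) == 0L) stop("empty profile: no peaks")
  if (anyNA(peaks)) stop("profile peaks contain NA")
  peaks <- peaks[order(peaks$size), , drop = FALSE]
  rownames(peaks) <- NULL
  if (anyDuplicated(peaks$size)) stop("duplicate T-RF sizes in profile")
  if (any(peaks$abundance < 0)) stop("negative abundance in profile")
  if (abs(sum(peaks$abundance) - 100) > 1e-6)
    stop("profile abundances must sum to 100 (got ", format(sum(peaks$abundance)), ")")
  size_range <- as.integer(size_range)
  if (any(peaks$size < size_range[1]) || any(peaks$size > size_range[2]))
    stop("T-RF sizes outside size_range [", size_range[1], ",", size_range[2], "]")
  structure(list(sample_id = as.character(sample_id), kind = kind,
                 peaks = peaks, size_range = size_range),
            class = "trflp_profile")
}

#' @export
print.trflp_profile <- function(x, ...) {
  cat(sprintf("<trflp_profile> %s (%s): %d T-RFs in [%d, %d] bp\n",
              x$sample_id, x$kind, nrow(x$peaks), x$size_range[1], x$size_range[2]))
  top <- x$peaks[order(-x$peaks$abundance), , drop = FALSE]
  top <- utils::head(top, 5L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %4d bp  %6.2f %%\n", top$size[i], top$abundance[i]))
  if (nrow(x$peaks) > 5L) cat("  ...\n")
  invisible(x)
}

# renormalize a peak table to sum 100; assumes validated sizes
renormalize_peaks <- function(peaks) {
  tot <- sum(peaks$abundance)
  if (tot <= 0) stop("empty profile: total abundance is zero")
  peaks$abundance <- 100 * peaks$abundance / tot
  peaks
}

# half-up rounding to integer (electropherogram bp bins)
round_half_up <- function(x) floor(x + 0.5)

# half-up rounding to `digits` decimals (printed-table convention)
round1 <- function(x, digits = 1L) floor(x * 10^digits + 0.5) / 10^digits

#' Write a T-RFLP profile to CSV
#'
#' Two columns, `size` and `abundance`, abundance printed with 6 decimals so
#' that write/read round-trips are bit-stable.
#'
#' @param profile a [trflp_profile].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "trflp_profile"))
  df <- data.frame(size = profile$peaks$size,
                   abundance = sprintf("%.6f", profile$peaks$abundance))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
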