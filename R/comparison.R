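#' Bin a profile onto an integer-bp abundance vector
#'
#' Places each peak in its 1-bp bin over the inclusive `range` (default
#' 50-500 bp, 451 entries), drops peaks outside the range, and renormalizes
#' the remaining abundances to sum to 100. This is the representation used
#' for cross-correlation.
#'
#' @param profile a [trflp_profile].
#' @param range inclusive size window in bp.
#' @param bin bin width in bp (1 bp: electropherogram resolution).
#' @return named numeric vector, one entry per integer size.
#' @export
profile_to_vector <- function(profile, range = c(50L, 500L), bin = 1L) {
  stopifnot(inherits(profile, "trflp_profile"), bin == 1L)
  sizes <- range[1]:range[2]
  v <- stats::setNames(numeric(length(sizes)), sizes)
  pk <- profile$peaks[profile$peaks$size >= range[1] & profile$peaks$size <= range[2], ,
                      drop = FALSE]
  if (nrow(pk) == 0L) stop("empty profile after restriction to [",
                           range[1], ",", range[2], "] bp")
  v[as.character(pk$size)] <- pk$abundance
  100 * v / sum(v)
}

#' Cross-correlate digital and experimental fingerprint vectors
#'
#' Estimates the electrophoretic drift between a digital and an experimental
#' profile: for each integer lag `l` in `[-max_lag, max_lag]` the
#' cosine-normalized cross-correlation
#' `coefficient(l) = sum_i d[i - l] * e[i] / (||d|| * ||e||)`
#' is computed (out-of-range indices contribute 0). `coefficient(l)` is thus
#' the cosine similarity between the digital profile *shifted by `l`*
#' ([apply_shift()] with the same `l`) and the experimental profile, so a
#' pure translation of identical profiles scores exactly 1 at the matching
#' lag, and the optimal lag can be passed straight to [apply_shift()].
#' Digital fragments run a few bp longer than electrophoresis reports, so
#' recovered lags are negative (typically -4 to -6 bp); the default +/-20 bp
#' search window contains that drift comfortably. Ties resolve to the
#' smallest `|l|`, then to the negative lag.
#'
#' @param dvec,evec equal-length abundance vectors from
#'   [profile_to_vector()] (digital and experimental).
#' @param max_lag maximum absolute lag searched, in bp.
#' @return A list of class `trf_xcorr`: `lags`, `coefficients`,
#'   `optimal_lag`, `max_coefficient`.
#' @export
cross_correlate <- function(dvec, evec, max_lag = 20L) {
  stopifnot(length(dvec) == length(evec))
  nd <- sqrt(sum(dvec^2)); ne <- sqrt(sum(evec^2))
  if (nd == 0 || ne == 0) stop("zero-norm profile vector")
  n <- length(dvec)
  lags <- (-max_lag):max_lag
  coef <- vapply(lags, function(l) {
    i <- seq_len(n)
    j <- i - l
    ok <- j >= 1L & j <= n
    sum(dvec[j[ok]] * evec[i[ok]]) / (nd * ne)
  }, numeric(1))
  best <- max(coef)
  cand <- which(coef >= best - 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  opt <- lags[cand[1]]
  structure(list(lags = lags, coefficients = coef,
                 optimal_lag = as.integer(opt),
                 max_coefficient = coef[cand[1]]),
            class = "trf_xcorr")
}

#' @export
print.trf_xcorr <- function(x, ...) {
  cat(sprintf("<trf_xcorr> optimal lag %+d bp, max coefficient %.3f (window %+d..%+d)\n",
              x$optimal_lag, x$max_coefficient, min(x$lags), max(x$lags)))
  invisible(x)
}

#' Shift a digital profile by a drift lag
#'
#' Adds `lag` to every T-RF size (the lag from [cross_correlate()] is
#' negative when digital fragments run longer than experimental ones).
#' Peaks pushed outside the profile's size range are dropped with a warning
#' and the remainder renormalized.
#'
#' @param profile a digital [trflp_profile].
#' @param lag integer bp, from [cross_correlate()] or set by the user.
#' @return the shifted [trflp_profile].
#' @export
apply_shift <- function(profile, lag) {
  stopifnot(inherits(profile, "trflp_profile"))
  lag <- as.integer(lag)
  if (lag == 0L) return(profile)
  pk <- profile$peaks
  pk$size <- pk$size + lag
  out <- pk$size < profile$size_range[1] | pk$size > profile$size_range[2]
  if (any(out))
    warning(sum(out), " T-RF(s) shifted outside [", profile$size_range[1], ",",
            profile$size_range[2], "] bp dropped")
  pk <- pk[!out, , drop = FALSE]
  if (nrow(pk) == 0L) stop("empty profile: all T-RFs shifted out of range")
  trflp_profile(renormalize_peaks(pk), sample_id = profile$sample_id,
                kind = profile$kind, size_range = profile$size_range)
}

#' Match experimental T-RFs to shifted digital T-RFs
#'
#' Greedy nearest-size matching within a tolerance: candidate pairs within
#' `tolerance` bp are taken in order of increasing distance (ties toward the
#' smaller digital size), each peak used at most once.
#'
#' @param eprofile experimental [trflp_profile].
#' @param shifted_dprofile drift-corrected digital [trflp_profile].
#' @param tolerance maximum size difference in bp (default 1; mirror plots
#'   routinely show residual 1-bp offsets).
#' @return `list(matches, unmatched_etrfs, unmatched_dtrfs,
#'   percent_affiliated)`; `matches` has columns `etrf_size`,
#'   `shifted_dtrf_size`, `distance`; `percent_affiliated` is
#'   `100 * matched / experimental richness`.
#' @export
match_peaks <- function(eprofile, shifted_dprofile, tolerance = 1L) {
  es <- eprofile$peaks$size
  ds <- shifted_dprofile$peaks$size
  cand <- expand.grid(e = es, d = ds)
  cand$dist <- abs(cand$e - cand$d)
  cand <- cand[cand$dist <= tolerance, , drop = FALSE]
  cand <- cand[order(cand$dist, cand$d), , drop = FALSE]
  used_e <- used_d <- integer(0)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    if (cand$e[i] %in% used_e || cand$d[i] %in% used_d) next
    used_e <- c(used_e, cand$e[i]); used_d <- c(used_d, cand$d[i])
    rows[[length(rows) + 1L]] <- data.frame(etrf_size = cand$e[i],
                                            shifted_dtrf_size = cand$d[i],
                                            distance = cand$dist[i])
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(etrf_size = integer(0), shifted_dtrf_size = integer(0),
               distance = integer(0))
  matches <- matches[order(matches$etrf_size), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_etrfs = setdiff(es, matches$etrf_size),
       unmatched_dtrfs = setdiff(ds, matches$shifted_dtrf_size),
       percent_affiliated = 100 * nrow(matches) / length(es))
}

#' Paired mirror-plot table
#'
#' One row per integer size over the shared range, carrying the experimental
#' (up) and digital (down) abundances, plus display columns clipped at
#' `clip` percent - tall peaks are drawn truncated with their true abundance
#' annotated beside them.
#'
#' @param eprofile experimental [trflp_profile].
#' @param shifted_dprofile shifted digital [trflp_profile].
#' @param clip display ceiling in percent (default 5).
#' @return data frame with columns `size`, `e_abundance`, `d_abundance`,
#'   `e_display`, `d_display`, `e_clipped`, `d_clipped`.
#' @export
mirror_data <- function(eprofile, shifted_dprofile, clip = 5) {
  range <- eprofile$size_range
  ev <- profile_to_vector(eprofile, range = range)
  dv <- profile_to_vector(shifted_dprofile, range = range)
  data.frame(size = range[1]:range[2],
             e_abundance = unname(ev), d_abundance = unname(dv),
             e_display = pmin(unname(ev), clip), d_display = pmin(unname(dv), clip),
             e_clipped = unname(ev) > clip, d_clipped = unname(dv) > clip)
}
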