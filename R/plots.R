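#' Mirror plot of experimental vs shifted digital profiles
#'
#' Experimental abundances point up, shifted digital abundances down, on a
#' shared fragment-size axis; peaks taller than the display ceiling are
#' truncated and annotated with their true abundance.
#'
#' @param mirror table from [mirror_data()].
#' @param clip display ceiling in percent (must match the one used to build
#'   `mirror`'s display columns).
#' @param main plot title.
#' @return invisibly, `mirror`.
#' @export
plot_mirror <- function(mirror, clip = 5, main = "eT-RFLP (up) vs dT-RFLP (down)") {
  plot(NA, xlim = range(mirror$size), ylim = c(-clip, clip) * 1.15,
       xlab = "T-RF size (bp)", ylab = "relative abundance (%)", main = main)
  graphics::abline(h = 0, col = "grey50")
  graphics::segments(mirror$size, 0, mirror$size, mirror$e_display, col = "steelblue4")
  graphics::segments(mirror$size, 0, mirror$size, -mirror$d_display, col = "firebrick3")
  up <- mirror[mirror$e_clipped, ]
  dn <- mirror[mirror$d_clipped, ]
  if (nrow(up)) graphics::text(up$size, clip * 1.08,
                               sprintf("%.0f", up$e_abundance), cex = 0.6)
  if (nrow(dn)) graphics::text(dn$size, -clip * 1.08,
                               sprintf("%.0f", dn$d_abundance), cex = 0.6)
  invisible(mirror)
}

#' Plot cross-correlation coefficients against lag
#'
#' @param xcorr a `trf_xcorr` from [cross_correlate()].
#' @return invisibly, `xcorr`.
#' @export
plot_xcorr <- function(xcorr) {
  plot(xcorr$lags, xcorr$coefficients, type = "h", lwd = 2,
       xlab = "lag (bp)", ylab = "cross-correlation coefficient",
       main = sprintf("optimal lag %+d bp", xcorr$optimal_lag))
  graphics::points(xcorr$optimal_lag, xcorr$max_coefficient, pch = 19, col = "firebrick3")
  invisible(xcorr)
}

#' Plot a T-RF density report
#'
#' Histogram of T-RFs per 50-bp class with the cumulative richness curve
#' overlaid (right axis ends at the richness index).
#'
#' @param report a `density_report`.
#' @return invisibly, `report`.
#' @export
plot_density_report <- function(report) {
  cl <- report$classes
  mids <- (cl$lower + cl$upper) / 2
  bp <- graphics::barplot(cl$count, names.arg = paste0(cl$lower, "-", cl$upper),
                          las = 2, cex.names = 0.7,
                          ylab = "T-RFs per 50-bp class",
                          main = sprintf("%s: richness %d (H' %.2f)",
                                         if (is.null(report$enzyme)) "" else report$enzyme,
                                         report$indices$richness, report$indices$shannon))
  graphics::lines(bp, cl$cumulative * max(cl$count) / max(cl$cumulative),
                  lwd = 2)
  invisible(report)
}
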