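#' Pipeline configuration
#'
#' Bundles every knob of the fingerprinting workflow. Three presets mirror
#' the standard processing comparisons: `"standard"` (denoising on, SW score
#' filter at 150), `"filtered"` (no denoising, SW filter 150) and `"raw"`
#' (no denoising, SW threshold 0 - every mapped-or-not read is digested).
#'
#' @param reads_path path to the FASTA/FASTQ reads file.
#' @param db_path path to the taxonomy-annotated reference FASTA.
#' @param etrflp_path optional path to the experimental profile CSV; when
#'   `NULL` the pipeline runs in no-eT-RFLP mode (annotation without shift).
#' @param out_dir output directory (created if absent).
#' @param procedure preset, one of `"standard"`, `"filtered"`, `"raw"`.
#' @param enzyme enzyme name resolved via [get_enzyme()].
#' @param fwd_primer,rev_primer optional primers for [trim_primers()].
#' @param filter_cfg a [quality_filter_config()].
#' @param scheme a [scoring_scheme()].
#' @param min_sw_score SW score filter (overridden by the preset unless set
#'   explicitly).
#' @param cluster_identity denoising identity threshold.
#' @param skip_denoise force denoising off regardless of preset.
#' @param shift manual drift override in bp; `NULL` uses the optimal
#'   cross-correlation lag.
#' @param max_lag cross-correlation search window in bp.
#' @param match_tolerance peak-matching tolerance in bp.
#' @param origin_offset added to every fragment size, see [first_cut()].
#' @param size_range comparison window in bp.
#' @param sample_id sample identifier.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads_path, db_path, etrflp_path = NULL,
                            out_dir = tempfile("trfid_"),
                            procedure = c("standard", "filtered", "raw"),
                            enzyme = "HaeIII",
                            fwd_primer = NULL, rev_primer = NULL,
                            filter_cfg = quality_filter_config(),
                            scheme = scoring_scheme(),
                            min_sw_score = NULL, cluster_identity = 0.97,
                            skip_denoise = FALSE, shift = NULL, max_lag = 20L,
                            match_tolerance = 1L, origin_offset = 0L,
                            size_range = c(50L, 500L), sample_id = NULL) {
  procedure <- match.arg(procedure)
  denoise <- switch(procedure, standard = TRUE, filtered = FALSE, raw = FALSE)
  if (skip_denoise) denoise <- FALSE
  if (is.null(min_sw_score))
    min_sw_score <- switch(procedure, standard = 150, filtered = 150, raw = 0)
  if (is.null(sample_id))
    sample_id <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(reads_path),
                     ignore.case = TRUE)
  structure(list(reads_path = reads_path, db_path = db_path,
                 etrflp_path = etrflp_path, out_dir = out_dir,
                 procedure = procedure, enzyme = enzyme,
                 fwd_primer = fwd_primer, rev_primer = rev_primer,
                 filter_cfg = filter_cfg, scheme = scheme,
                 min_sw_score = min_sw_score,
                 cluster_identity = cluster_identity, denoise = denoise,
                 shift = shift, max_lag = as.integer(max_lag),
                 match_tolerance = as.integer(match_tolerance),
                 origin_offset = as.integer(origin_offset),
                 size_range = as.integer(size_range), sample_id = sample_id),
            class = "pipeline_config")
}

#' Run the full fingerprinting pipeline
#'
#' Executes, in order: read parsing, optional primer trimming, quality and
#' length filtering, optional denoising into centroid clusters,
#' Smith-Waterman best-hit mapping, in-silico digestion into a raw digital
#' profile, and - when an experimental profile is supplied - the 50-500 bp
#' digital profile, cross-correlation drift estimation, profile shifting,
#' peak matching and the peak-annotation table. All result files are written
#' under `config$out_dir` and listed in a JSON manifest; re-running with the
#' same configuration and inputs reproduces them byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of class `pipeline_result` with elements
#'   `filter_stats`, `clusters`, `mapping`, `digest`, `raw_profile`,
#'   `profile`, `xcorr`, `lag`, `shifted_profile`, `matches`, `annotations`,
#'   `indices`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$reads_path, config$db_path, config$etrflp_path))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$out_dir, name)
  manifest <- character(0)
  log_msg <- function(...) message("[trfid] ", sprintf(...))

  reads <- read_sequences(config$reads_path)
  log_msg("%d reads in", nrow(reads))
  n_primer_rejected <- 0L
  if (!is.null(config$fwd_primer)) {
    tr <- trim_primers(reads, config$fwd_primer, config$rev_primer)
    n_primer_rejected <- nrow(tr$rejected)
    reads <- tr$reads
    log_msg("primer trimming: %d kept, %d rejected", nrow(reads), n_primer_rejected)
  }
  qf <- quality_filter(reads, config$filter_cfg)
  log_msg("quality filter: %d kept of %d", qf$stats$kept, qf$stats$input)
  if (nrow(qf$reads) == 0L)
    stop("empty pipeline: no reads passed filtering", call. = FALSE)

  filter_stats <- data.frame(
    sample = config$sample_id, reads_in = nrow(reads) + n_primer_rejected,
    primer_rejected = n_primer_rejected,
    rejected_short = qf$stats$rejected_short,
    rejected_long = qf$stats$rejected_long,
    rejected_quality = qf$stats$rejected_quality,
    no_quality = qf$stats$no_quality, kept = qf$stats$kept)
  utils::write.csv(filter_stats, outfile("filtering_stats.csv"), row.names = FALSE)
  manifest <- c(manifest, "filtering_stats.csv")

  clusters <- if (config$denoise) {
    denoise_cluster(qf$reads, identity = config$cluster_identity)
  } else reads_as_clusters(qf$reads)
  log_msg("%d clusters (denoise=%s)", nrow(clusters), config$denoise)

  db <- read_reference_db(config$db_path)
  mapping <- map_clusters(clusters, db, scheme = config$scheme,
                          min_score = config$min_sw_score)
  log_msg("mapping: %d/%d clusters mapped (min SW %s)", mapping$stats$mapped,
          mapping$stats$queries, config$min_sw_score)
  write_mapping_report(mapping, outfile("mapping_stats.csv"),
                       outfile("unmapped.txt"), sample_id = config$sample_id)
  manifest <- c(manifest, "mapping_stats.csv", "unmapped.txt")
  if (nrow(mapping$hits) == 0L)
    stop("empty pipeline: no clusters mapped", call. = FALSE)

  enzyme <- get_enzyme(config$enzyme)
  digest <- digest_dataset(clusters, hits = mapping$hits, enzyme = enzyme,
                           origin_offset = config$origin_offset)
  log_msg("digestion: %d T-RFs, %d reads in site-free clusters discarded",
          nrow(digest$trfs), digest$discarded)
  if (nrow(digest$trfs) == 0L)
    stop("empty pipeline: no restriction sites found", call. = FALSE)
  raw_profile <- build_profile(digest, sample_id = config$sample_id,
                               size_range = c(1L, config$size_range[2]))
  write_profile(raw_profile, outfile("dtrflp_raw.csv"))
  manifest <- c(manifest, "dtrflp_raw.csv")

  xcorr <- NULL; lag <- NULL; shifted <- NULL; matches <- NULL
  eprof <- NULL
  profile <- build_profile(digest, sample_id = config$sample_id,
                           size_range = config$size_range)
  if (!is.null(config$etrflp_path)) {
    eprof <- read_etrflp(config$etrflp_path, size_range = config$size_range)
    xcorr <- cross_correlate(profile_to_vector(profile, config$size_range),
                             profile_to_vector(eprof, config$size_range),
                             max_lag = config$max_lag)
    lag <- if (!is.null(config$shift)) as.integer(config$shift) else xcorr$optimal_lag
    log_msg("cross-correlation: optimal lag %+d (max %.3f), applied lag %+d",
            xcorr$optimal_lag, xcorr$max_coefficient, lag)
    utils::write.csv(data.frame(lag = xcorr$lags, coefficient = xcorr$coefficients),
                     outfile("crosscorrelation.csv"), row.names = FALSE)
    shifted <- apply_shift(profile, lag)
    matches <- match_peaks(eprof, shifted, tolerance = config$match_tolerance)
    log_msg("%.1f%% of eT-RFs affiliated", matches$percent_affiliated)
    utils::write.csv(mirror_data(eprof, shifted), outfile("mirror.csv"),
                     row.names = FALSE)
    manifest <- c(manifest, "crosscorrelation.csv", "mirror.csv")
  }

  annotations <- annotate_trfs(digest, lag = lag, matches = matches)
  write_annotations(annotations, outfile("peak_annotations.csv"))
  manifest <- c(manifest, "peak_annotations.csv")

  idx_profile <- if (!is.null(shifted)) shifted else profile
  idx <- profile_indices(idx_profile)
  raw_idx <- profile_indices(raw_profile)
  indices <- data.frame(
    sample = config$sample_id, procedure = config$procedure,
    richness = idx$richness, shannon = idx$shannon,
    raw_richness = raw_idx$richness, raw_shannon = raw_idx$shannon,
    percent_affiliated = if (!is.null(matches)) matches$percent_affiliated else NA_real_,
    optimal_lag = if (!is.null(xcorr)) xcorr$optimal_lag else NA_integer_,
    max_coefficient = if (!is.null(xcorr)) xcorr$max_coefficient else NA_real_)
  utils::write.csv(indices, outfile("indices.csv"), row.names = FALSE)
  manifest <- c(manifest, "indices.csv")

  jsonlite::write_json(list(sample = config$sample_id, out_dir = config$out_dir,
                            files = manifest),
                       outfile("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest <- c(manifest, "manifest.json")

  invisible(structure(list(
    config = config, filter_stats = filter_stats, clusters = clusters,
    mapping = mapping, digest = digest, raw_profile = raw_profile,
    profile = profile, etrflp = eprof, xcorr = xcorr, lag = lag,
    shifted_profile = shifted, matches = matches, annotations = annotations,
    indices = indices, manifest = manifest), class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> sample", x$config$sample_id,
      "(", x$config$procedure, "procedure )\n")
  cat(sprintf("  clusters: %d; mapped: %d; T-RFs: %d\n",
              nrow(x$clusters), nrow(x$mapping$hits), nrow(x$digest$trfs)))
  if (!is.null(x$xcorr))
    cat(sprintf("  lag %+d bp (coef %.3f); %.1f%% eT-RFs affiliated\n",
                x$lag, x$xcorr$max_coefficient, x$matches$percent_affiliated))
  cat("  outputs:", x$config$out_dir, "\n")
  invisible(x)
}
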