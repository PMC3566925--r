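#' Read amplicon sequences from FASTA or FASTQ
#'
#' Parses amplicon reads into a reads table, attaching per-base PHRED
#' qualities when the format carries them (FASTQ, PHRED+33; or a paired
#' `.qual` file for FASTA+QUAL input).
#'
#' @param path path to a FASTA or FASTQ file.
#' @param format one of `"auto"`, `"fasta"`, `"fastq"`, `"fasta+qual"`.
#'   `"auto"` decides from the file extension (`.fq`/`.fastq` vs the rest).
#' @param qual_path path to the `.qual` file for `format = "fasta+qual"`.
#' @return A data frame of class `trf_reads` with columns `id` (character),
#'   `sequence` (uppercase character) and `quality` (list column of integer
#'   PHRED vectors, or `NULL` entries when absent).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGTACGT", ">r2", "GGCCAATT"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq", "fasta+qual"),
                           qual_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"

  if (format == "fastq") {
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ '", path, "': ", conditionMessage(e)))
    quals <- lapply(as.character(S4Vectors::mcols(set)$qualities),
                    function(q) utf8ToInt(q) - 33L)
  } else {
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e)))
    quals <- vector("list", length(set))
    if (format == "fasta+qual") {
      if (is.null(qual_path)) stop("format 'fasta+qual' requires qual_path")
      quals <- read_qual_file(qual_path)
      ids <- sub("\\s.*$", "", names(set))
      if (!identical(names(quals), ids))
        stop("FASTA/QUAL id mismatch: ", paste(utils::head(setdiff(ids, names(quals))), collapse = ", "))
      quals <- unname(quals[ids])
    }
  }

  widths <- Biostrings::width(set)
  if (any(widths == 0L))
    stop("empty sequence at record ", which(widths == 0L)[1], " of '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  has_q <- !vapply(quals, is.null, logical(1))
  if (any(has_q)) {
    bad <- which(has_q & lengths(quals) != widths)
    if (length(bad))
      stop("quality length differs from sequence length at record ", bad[1])
  }
  reads <- data.frame(id = ids, sequence = toupper(as.character(set)),
                      stringsAsFactors = FALSE)
  reads$quality <- quals
  rownames(reads) <- NULL
  class(reads) <- c("trf_reads", "data.frame")
  reads
}

# parse a 454-style .qual file: FASTA headers, space-separated integers
read_qual_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("malformed QUAL file: no headers")
  idx <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  vals <- split(lines[!hdr], idx[!hdr])
  quals <- lapply(vals, function(v) as.integer(strsplit(paste(v, collapse = " "), "\\s+")[[1]]))
  names(quals) <- ids
  quals
}

#' Read an experimental T-RFLP profile from CSV
#'
#' Expects two columns: fragment size (bp) and abundance (percent or raw
#' peak area). A header row is auto-detected from a non-numeric first cell.
#' Sizes are rounded half-up to integer bp; duplicate sizes after rounding
#' are summed (with a warning); peaks outside `size_range` are dropped; the
#' remaining abundances are renormalized to sum to 100.
#'
#' @param path CSV file path.
#' @param sample_id sample identifier for the resulting profile.
#' @param size_range inclusive size window in bp (electropherogram calibration
#'   range; default 50-500).
#' @return A [trflp_profile] with `kind = "experimental"`.
#' @export
read_etrflp <- function(path, sample_id = basename(path), size_range = c(50L, 500L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- utils::read.csv(path, header = FALSE, nrows = 1, colClasses = "character")
  has_header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  df <- utils::read.csv(path, header = has_header, colClasses = "numeric")
  if (ncol(df) < 2) stop("eT-RFLP CSV must have (size, abundance) columns")
  df <- df[, 1:2]
  names(df) <- c("size", "abundance")
  if (anyNA(df)) stop("non-numeric cell in eT-RFLP CSV '", path, "'")
  if (any(df$abundance < 0)) stop("negative abundance in eT-RFLP CSV '", path, "'")
  df$size <- as.integer(round_half_up(df$size))
  if (anyDuplicated(df$size)) {
    warning("duplicate sizes after rounding in '", path, "'; abundances summed")
    df <- stats::aggregate(abundance ~ size, data = df, FUN = sum)
  }
  df <- df[df$size >= size_range[1] & df$size <= size_range[2], , drop = FALSE]
  if (nrow(df) == 0L) stop("no eT-RFs within [", size_range[1], ",", size_range[2], "] bp")
  trflp_profile(renormalize_peaks(df), sample_id = sample_id,
                kind = "experimental", size_range = size_range)
}

#' Read a taxonomy-annotated reference database from FASTA
#'
#' Headers are expected in a pipe-delimited `otu_id|accession|taxonomy`
#' layout (Greengenes-style), where the taxonomy string is a `;`-separated
#' list of rank-prefixed labels (`P:`, `C:`, `O:`, `F:`, `G:`, `S:`). A
#' custom `header_parser` may be supplied for other layouts; it receives one
#' header string and must return `list(otu_id=, accession=, taxonomy=)`.
#'
#' @param path reference FASTA path.
#' @param header_parser function parsing one FASTA header.
#' @return A data frame of class `ref_db` with columns `otu_id`, `accession`,
#'   `taxonomy` and `sequence`. Records with no taxonomy are kept with
#'   taxonomy `"unclassified"` (with a warning); duplicate accessions are an
#'   error.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">4015|GQ396926|F:Xanthomonadaceae", "ACGTACGTACGT"), fa)
#' read_reference_db(fa)
#' @export
read_reference_db <- function(path, header_parser = parse_ref_header) {
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed reference FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty database: '", path, "'")
  parsed <- lapply(names(set), header_parser)
  db <- data.frame(
    otu_id = vapply(parsed, function(p) p$otu_id, character(1)),
    accession = vapply(parsed, function(p) p$accession, character(1)),
    taxonomy = vapply(parsed, function(p) p$taxonomy, character(1)),
    sequence = toupper(as.character(set)),
    stringsAsFactors = FALSE)
  rownames(db) <- NULL
  if (any(db$taxonomy == "unclassified"))
    warning("record(s) without taxonomy kept as 'unclassified': ",
            paste(utils::head(db$accession[db$taxonomy == "unclassified"], 3), collapse = ", "))
  dup <- db$accession[duplicated(db$accession)]
  if (length(dup)) stop("duplicate accession in reference database: ", dup[1])
  class(db) <- c("ref_db", "data.frame")
  db
}

#' Parse a pipe-delimited reference FASTA header
#'
#' @param header header string (without the leading `>`), laid out as
#'   `otu_id|accession|taxonomy`.
#' @return `list(otu_id, accession, taxonomy)`; missing taxonomy yields
#'   `"unclassified"`.
#' @export
parse_ref_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (length(parts) < 2) stop("cannot parse reference header: '", header, "'")
  tax <- if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else "unclassified"
  list(otu_id = parts[1], accession = parts[2], taxonomy = tax)
}

#' Split a rank-prefixed taxonomy string into named ranks
#'
#' @param taxonomy string such as `"P:Proteobacteria;G:Acidovorax"`.
#' @return named character vector; names are rank codes (`P`, `C`, `O`, `F`,
#'   `G`, `S`) or `rank<i>` when unprefixed.
#' @export
split_taxonomy <- function(taxonomy) {
  parts <- trimws(strsplit(taxonomy, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return(c(rank1 = "unclassified"))
  has_prefix <- grepl("^[PCOFGS]:", parts)
  nm <- ifelse(has_prefix, sub(":.*$", "", parts), paste0("rank", seq_along(parts)))
  val <- ifelse(has_prefix, trimws(sub("^[PCOFGS]:", "", parts)), parts)
  stats::setNames(val, nm)
}

#' Write reads to FASTA or FASTQ
#'
#' FASTQ is written when every read carries qualities (PHRED+33), otherwise
#' FASTA.
#'
#' @param reads a `trf_reads` table from [read_sequences()] or
#'   [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path) {
  has_q <- !vapply(reads$quality, is.null, logical(1))
  con <- file(path, "w")
  on.exit(close(con))
  if (all(has_q) && nrow(reads) > 0L) {
    for (i in seq_len(nrow(reads)))
      writeLines(c(paste0("@", reads$id[i]), reads$sequence[i], "+",
                   intToUtf8(reads$quality[[i]] + 33L)), con)
  } else {
    for (i in seq_len(nrow(reads)))
      writeLines(c(paste0(">", reads$id[i]), reads$sequence[i]), con)
  }
  invisible(path)
}

#' Write a reference database to FASTA
#'
#' @param db a `ref_db` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(db)))
    writeLines(c(sprintf(">%s|%s|%s", db$otu_id[i], db$accession[i], db$taxonomy[i]),
                 db$sequence[i]), con)
  invisible(path)
}
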