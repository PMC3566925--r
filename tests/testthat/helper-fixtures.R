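# small in-code fixtures shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]])))
  writeLines(as.character(lines), path)
  path
}

write_tmp_fastq <- function(ids, seqs, qual_chars, path = tempfile(fileext = ".fastq")) {
  writeLines(unlist(mapply(function(i, s, q) c(paste0("@", i), s, "+", q),
                           ids, seqs, qual_chars, SIMPLIFY = FALSE)), path)
  path
}

make_reads <- function(seqs, ids = sprintf("r%d", seq_along(seqs)), quals = NULL) {
  reads <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
  reads$quality <- if (is.null(quals)) vector("list", length(seqs)) else quals
  class(reads) <- c("trf_reads", "data.frame")
  reads
}

# a deterministic 4-taxon toy community used by several integration tests
toy_community <- function(seed = 42, read_count = 120, sub = 0.004, hp = 0.02) {
  ref <- make_reference_db(n_taxa = 4, length = 480,
                           site_positions = c(80L, 120L, 160L, 200L), seed = seed)
  ab <- c(0.4, 0.3, 0.2, 0.1)
  spec <- community_spec(ref$db, ab, read_count = read_count,
                         substitution_rate = sub, homopolymer_indel_rate = hp,
                         seed = seed + 1)
  sim <- simulate_reads(spec)
  list(ref = ref, abundances = ab, sim = sim)
}

realized_abundances <- function(sim, db) {
  tab <- table(factor(sim$truth$accession, levels = db$accession))
  as.numeric(tab) / sum(tab)
}
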