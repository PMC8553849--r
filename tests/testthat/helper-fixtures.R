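# Small in-code fixtures shared across tests.

tiny_ref <- function(seq = NULL, name = "chrT", len = 300L) {
  fa <- tempfile(fileext = ".fa")
  if (is.null(seq)) {
    set.seed(42)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
  }
  writeLines(c(paste0(">", name), seq), fa)
  load_reference(fa)
}

# One alignment record as a named list (internal 0-based pos).
make_record <- function(qname = "r1", flag = 0L, rname = "chrT", pos = 10L,
                        mapq = 60L, cigar = "10M", rnext = "*", pnext = -1L,
                        tlen = 0L, seq = strrep("A", 10), qual = strrep("F", 10),
                        tags = character()) {
  list(qname = qname, flag = flag, rname = rname, pos = as.integer(pos),
       mapq = as.integer(mapq), cigar = cigar, rnext = rnext,
       pnext = as.integer(pnext), tlen = as.integer(tlen), seq = seq,
       qual = qual, tags = tags)
}

# Write records (list of make_record lists) + header for a reference to SAM
# or BAM on disk.
write_tiny_alignments <- function(ref, records, ext = ".bam", sort = TRUE) {
  header <- c("@HD\tVN:1.6",
              paste0("@SQ\tSN:", ref$contigs$name, "\tLN:", ref$contigs$length))
  tbl <- bamscrub:::records_from_list(records)
  path <- tempfile(fileext = ext)
  write_alignments(header, tbl, path, sort = sort)
  path
}

small_sim_params <- function(seed, ...) {
  defaults <- list(seed = seed, contig_len = 20000L, n_snps = 12L,
                   n_insertions = 5L, n_deletions = 5L, n_reads = 160L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}
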