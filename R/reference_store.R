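#' Load a reference genome from FASTA
#'
#' Reads a (possibly soft-masked, multi-record) FASTA file into an in-memory,
#' uppercased sequence store with constant-time region fetch. A `.fai` index
#' sidecar is created next to the file if absent, so downstream htslib-based
#' tools (pileup, `samtools calmd`, ...) can address the same file.
#'
#' All coordinates used with the returned object are 0-based half-open;
#' conversion to the 1-based SAM text convention happens only at the I/O
#' boundary.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_reference` object. Its `contigs` element is a tibble with
#'   columns `name` and `length` (bp), in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "ACGTacgt"), fa)
#' ref <- load_reference(fa)
#' ref_contigs(ref)
#' ref_fetch(ref, "chrT", 0, 8)
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) {
    stop("reference FASTA not found: ", path, call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  # FASTA headers may carry descriptions after the first whitespace
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in reference: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  fai <- paste0(path, ".fai")
  if (!file.exists(fai)) {
    tryCatch(Rsamtools::indexFa(path), error = function(e) invisible(NULL))
  }
  structure(
    list(
      seq = stats::setNames(toupper(as.character(seqs)), nm),
      contigs = tibble::tibble(name = nm, length = Biostrings::width(seqs)),
      path = normalizePath(path)
    ),
    class = "genome_reference"
  )
}

#' @export
print.genome_reference <- function(x, ...) {
  cat("<genome_reference> ", nrow(x$contigs), " contig(s), ",
      sum(x$contigs$length), " bp total\n", sep = "")
  print(x$contigs, ...)
  invisible(x)
}

#' Contig table of a reference
#'
#' @param ref A `genome_reference`.
#' @return A tibble with columns `name`, `length`.
#' @export
ref_contigs <- function(ref) {
  stopifnot(inherits(ref, "genome_reference"))
  ref$contigs
}

#' Fetch reference sequence for a region
#'
#' @param ref A `genome_reference`.
#' @param contig Contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end. `ref_fetch(ref, c, s, s)` returns `""`.
#' @return Uppercase sequence string of exactly `end - start` characters.
#' @export
ref_fetch <- function(ref, contig, start, end) {
  stopifnot(inherits(ref, "genome_reference"))
  if (!contig %in% names(ref$seq)) stop("unknown contig: ", contig, call. = FALSE)
  s <- ref$seq[[contig]]
  len <- nchar(s)
  if (start < 0 || end < start || end > len) {
    stop("out-of-bounds fetch on ", contig, ":", start, "-", end,
         " (contig length ", len, ")", call. = FALSE)
  }
  if (end == start) return("")
  substr(s, start + 1L, end)
}

#' Length of a contig
#' @param ref A `genome_reference`.
#' @param contig Contig name.
#' @return Integer length in bp.
#' @export
ref_length <- function(ref, contig) {
  i <- match(contig, ref$contigs$name)
  if (is.na(i)) stop("unknown contig: ", contig, call. = FALSE)
  ref$contigs$length[[i]]
}

#' Write a reference back to FASTA
#'
#' Round-trip companion of [load_reference()]: reloading the written file
#' yields identical `ref_fetch()` results.
#'
#' @param ref A `genome_reference`.
#' @param path Output FASTA path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, width = 70L) {
  x <- Biostrings::DNAStringSet(ref$seq)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
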