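# Independent audit of residual genetic variation. The pileup is computed by
# the htslib pileup engine (Rsamtools), not by the package's own rewrite
# code, so it serves as a ground-truth check on the sanitizer: deletions
# count as non-reference evidence over their reference span ('-' rows),
# insertions anchored at the base before the event ('+' rows). Base quality
# is ignored throughout — the claim audited is absolute absence, not
# statistical.

#' Per-position base counts from a BAM
#'
#' Tallies A/C/G/T/N read bases for every covered reference position from
#' M-type alignment columns (splice gaps contribute nothing, soft-clipped
#' bases are excluded), plus `-` rows over deleted spans and `+` rows at
#' insertion anchors. No base-quality or mapping-quality threshold is
#' applied.
#'
#' @param bam Path to an indexed BAM.
#' @param max_depth Per-position depth cap (set high: the audit must see
#'   every read).
#' @return Tibble `contig`, `pos` (0-based), `nucleotide`, `count`.
#' @export
pileup_counts <- function(bam, max_depth = 1000000L) {
  if (!file.exists(paste0(bam, ".bai"))) Rsamtools::indexBam(bam)
  pp <- Rsamtools::PileupParam(
    max_depth = max_depth, min_base_quality = 0L, min_mapq = 0L,
    min_nucleotide_depth = 1L, min_minor_allele_depth = 0L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = FALSE, include_deletions = TRUE,
    include_insertions = TRUE)
  p <- Rsamtools::pileup(bam, pileupParam = pp)
  tibble::tibble(contig = as.character(p$seqnames), pos = p$pos - 1L,
                 nucleotide = as.character(p$nucleotide), count = p$count)
}

# Auditor-side CIGAR walk: does this record carry any non-reference evidence
# (I or D op, or a mismatching base in an M/=/X column)?
read_has_alt <- function(record, ref) {
  ops <- parse_cigar(record$cigar)
  if (any(ops$op %in% c("I", "D"))) return(TRUE)
  cur <- record$pos
  q <- 0L
  for (i in seq_len(nrow(ops))) {
    o <- ops$op[i]; l <- ops$len[i]
    if (o %in% c("M", "=", "X")) {
      if (substr(record$seq, q + 1L, q + l) !=
          ref_fetch(ref, record$rname, cur, cur + l)) return(TRUE)
      q <- q + l; cur <- cur + l
    } else if (o == "S") {
      q <- q + l
    } else if (o == "N") {
      cur <- cur + l
    }
  }
  FALSE
}

#' Check that a record is byte-identical to the reference
#'
#' TRUE iff the record's CIGAR uses only M and N and its sequence equals the
#' concatenated reference fetch over its M blocks. A record whose CIGAR still
#' contains any other op is not sanitized and returns FALSE (with the reason
#' in the `"reason"` attribute).
#'
#' @param record Named record list (one row of a record tibble).
#' @param ref A `genome_reference`.
#' @return Logical scalar, possibly with a `"reason"` attribute when FALSE.
#' @export
verify_sequence_identity <- function(record, ref) {
  ops <- parse_cigar(record$cigar)
  extra <- setdiff(unique(ops$op), c("M", "N"))
  if (length(extra)) {
    return(structure(FALSE, reason = paste0("non-sanitized CIGAR op(s): ",
                                            paste(extra, collapse = ","))))
  }
  cur <- record$pos
  expect <- character()
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] == "M") {
      expect <- c(expect, ref_fetch(ref, record$rname, cur, cur + ops$len[i]))
    }
    cur <- cur + ops$len[i]
  }
  identical(record$seq, paste(expect, collapse = ""))
}

#' Audit a BAM for residual non-reference variation
#'
#' The package's validation endpoint: pileup every covered position against
#' the reference and report any position with non-reference read support
#' (mismatching base, insertion, or deletion; support threshold 1 read), and
#' every read contributing non-reference evidence.
#'
#' @param bam Path to an indexed, coordinate-sorted BAM.
#' @param ref A `genome_reference` or FASTA path.
#' @return A `residual_report`: `positions_checked`, `residual` (tibble
#'   `contig`, `pos` 0-based, `ref`, `base`, `count`), `reads_total` (mapped
#'   records audited), `reads_with_alt`, `alt_read_fraction`. See
#'   [tidy()]/[glance()]/[autoplot()] methods and [write_residual_report()].
#' @export
residual_audit <- function(bam, ref) {
  if (!inherits(ref, "genome_reference")) ref <- load_reference(ref)
  pc <- pileup_counts(bam)
  if (nrow(pc) > 0) {
    refbase <- vapply(seq_len(nrow(pc)), function(i) {
      ref_fetch(ref, pc$contig[i], pc$pos[i], pc$pos[i] + 1L)
    }, character(1))
    nonref <- pc$nucleotide %in% c("+", "-") | pc$nucleotide != refbase
    residual <- tibble::tibble(contig = pc$contig[nonref],
                               pos = pc$pos[nonref],
                               ref = refbase[nonref],
                               base = pc$nucleotide[nonref],
                               count = pc$count[nonref])
    positions_checked <- nrow(dplyr::distinct(pc, .data$contig, .data$pos))
  } else {
    residual <- tibble::tibble(contig = character(), pos = integer(),
                               ref = character(), base = character(),
                               count = integer())
    positions_checked <- 0L
  }

  x <- read_alignments(bam)
  mapped <- x$records[!flag_has(x$records$flag, FLAG_UNMAPPED), ]
  reads_total <- nrow(mapped)
  reads_with_alt <- 0L
  for (i in seq_len(reads_total)) {
    if (read_has_alt(record_row(mapped, i), ref)) {
      reads_with_alt <- reads_with_alt + 1L
    }
  }
  structure(list(
    positions_checked = positions_checked,
    residual = residual,
    reads_total = reads_total,
    reads_with_alt = reads_with_alt,
    alt_read_fraction = if (reads_total > 0) reads_with_alt / reads_total else 0
  ), class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat("<residual_report>\n",
      "  positions checked: ", x$positions_checked, "\n",
      "  residual non-reference positions: ",
      length(unique(paste(x$residual$contig, x$residual$pos))), "\n",
      "  reads with alternate alleles: ", x$reads_with_alt, " / ",
      x$reads_total, " (fraction ", signif(x$alt_read_fraction, 4), ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy residual_report
#' @export
tidy.residual_report <- function(x, ...) {
  dplyr::mutate(x$residual, pos = .data$pos + 1L)  # 1-based for reporting
}

#' @method glance residual_report
#' @export
glance.residual_report <- function(x, ...) {
  tibble::tibble(
    positions_checked = x$positions_checked,
    residual_positions = length(unique(paste(x$residual$contig, x$residual$pos))),
    reads_total = x$reads_total,
    reads_with_alt = x$reads_with_alt,
    alt_read_fraction = x$alt_read_fraction
  )
}

#' @method autoplot residual_report
#' @export
autoplot.residual_report <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no residual non-reference support") +
             ggplot2::theme_void() +
             ggplot2::ggtitle("Residual variation audit"))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$count,
                                  fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~contig) +
    ggplot2::labs(x = "position (1-based)", y = "non-reference read support",
                  title = "Residual variation audit") +
    ggplot2::theme_minimal()
}

#' Write a residual report as TSV
#'
#' Columns `contig`, `pos` (1-based for reporting), `ref`, `base`, `count`.
#'
#' @param report A `residual_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residual_report <- function(report, path) {
  readr::write_tsv(tidy(report), path)
  invisible(path)
}
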