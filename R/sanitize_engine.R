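#' Sanitization options
#'
#' @param strict Also rewrite mapping quality and alignment-score-type tags
#'   (AS/MQ to read length, NH to 1, MAPQ to 255) and drop the extended tag
#'   set (HI, IH, H1, H2, OA, OC, OP, OQ, SA, SM, XA, XS).
#' @param keep_secondary Keep secondary and supplementary alignments instead
#'   of discarding them. Full protection against genotype inference cannot be
#'   guaranteed when multimappers are kept.
#' @param keep_unmapped Keep unmapped records. They carry no alignment to
#'   revert and are passed through (tags still sanitized); default discards
#'   them because their sequence cannot be cleared of variation.
#' @param hard_clip_qual Single quality character used to fill quality values
#'   for bases materialized from hard clips (default `"#"`, Phred 2).
#' @return A `sanitize_options` list.
#' @export
sanitize_options <- function(strict = FALSE, keep_secondary = FALSE,
                             keep_unmapped = FALSE, hard_clip_qual = "#") {
  stopifnot(is.logical(strict), is.logical(keep_secondary),
            is.logical(keep_unmapped),
            is.character(hard_clip_qual), nchar(hard_clip_qual) == 1L)
  structure(list(strict = strict, keep_secondary = keep_secondary,
                 keep_unmapped = keep_unmapped,
                 hard_clip_qual = hard_clip_qual),
            class = "sanitize_options")
}

layout_error <- function(reason, msg) {
  stop(structure(class = c("bamscrub_layout_error", "error", "condition"),
                 list(message = msg, call = NULL, reason = reason)))
}

#' Resolve the reference-identical geometry of an alignment
#'
#' Computes where a read's rewritten, variant-free sequence will sit on the
#' reference: an ordered set of match blocks separated by preserved splice
#' gaps, plus the (possibly adjusted) start position. The joint rules:
#' M/=/X map 1:1 into match blocks; I schedules an equal 3' extension; D
#' folds its reference span into the block and schedules an equal 3' trim;
#' N preserves the splice gap; P is dropped. A leading soft/hard clip moves
#' the start position left for single-end records but becomes a 3' extension
#' for paired records (5' positions of pairs must stay fixed to keep TLEN and
#' PNEXT valid); trailing clips always extend the 3' end. The net
#' extension/trim is applied at the rightmost reference coordinate; a trim
#' that consumes a whole terminal exon block removes that splice gap.
#' Read length is conserved: the blocks cover the stored sequence length plus
#' any hard-clipped length.
#'
#' @param cigar CIGAR string or parsed CIGAR tibble.
#' @param pos 0-based leftmost reference position.
#' @param paired Is the record flagged as paired?
#' @return A `resolved_layout` list: `new_pos`, `blocks` (tibble `ref_start`,
#'   `length`), `removed_splice`, `hard_clip_added`, `hard_fill_left`,
#'   `hard_fill_right`, `total_query_len`.
#' @export
resolve_layout <- function(cigar, pos, paired) {
  ops <- if (is.character(cigar)) parse_cigar(cigar) else cigar
  op <- ops$op; len <- ops$len
  n <- length(op)

  is_clip <- op %in% c("S", "H")
  lead_n <- 0L
  while (lead_n < n && is_clip[lead_n + 1L]) lead_n <- lead_n + 1L
  trail_n <- 0L
  while (trail_n < n - lead_n && is_clip[n - trail_n]) trail_n <- trail_n + 1L
  lead_idx  <- seq_len(lead_n)
  trail_idx <- if (trail_n > 0L) seq(n - trail_n + 1L, n) else integer()
  core_idx  <- setdiff(seq_len(n), c(lead_idx, trail_idx))

  lead_clip  <- sum(len[lead_idx])
  trail_clip <- sum(len[trail_idx])
  lead_H  <- sum(len[lead_idx][op[lead_idx] == "H"])
  trail_H <- sum(len[trail_idx][op[trail_idx] == "H"])

  # walk the core, folding D into blocks and breaking at N
  starts <- integer(); lens <- integer()
  cursor <- as.integer(pos)
  cur_start <- cursor; cur_len <- 0L
  ext <- 0L; trim <- 0L
  for (i in core_idx) {
    o <- op[i]; l <- len[i]
    if (o %in% c("M", "=", "X")) {
      cur_len <- cur_len + l; cursor <- cursor + l
    } else if (o == "D") {
      cur_len <- cur_len + l; cursor <- cursor + l; trim <- trim + l
    } else if (o == "I") {
      ext <- ext + l
    } else if (o == "N") {
      if (cur_len > 0L) { starts <- c(starts, cur_start); lens <- c(lens, cur_len) }
      cursor <- cursor + l
      cur_start <- cursor; cur_len <- 0L
    } else if (o == "P") {
      # consumes nothing
    } else {
      layout_error("degenerate", paste0("clip op '", o, "' inside alignment"))
    }
  }
  if (cur_len > 0L || length(starts) == 0L) {
    starts <- c(starts, cur_start); lens <- c(lens, cur_len)
  }

  # clips: leading moves the start for single-end, extends 3' for paired
  new_pos <- as.integer(pos)
  if (lead_clip > 0L) {
    if (!paired) {
      new_pos <- new_pos - lead_clip
      if (new_pos < 0L) {
        layout_error("out_of_range", "leading-clip adjustment before contig start")
      }
      starts[1] <- starts[1] - lead_clip
      lens[1] <- lens[1] + lead_clip
    } else {
      ext <- ext + lead_clip
    }
  }
  ext <- ext + trail_clip

  # apply net extension/trim at the rightmost reference coordinate
  net <- ext - trim
  removed_splice <- FALSE
  if (net > 0L) {
    lens[length(lens)] <- lens[length(lens)] + net
  } else if (net < 0L) {
    need <- -net
    while (need > 0L) {
      k <- length(lens)
      if (k == 0L) layout_error("degenerate", "trim exceeds whole layout")
      if (lens[k] > need) {
        lens[k] <- lens[k] - need
        need <- 0L
      } else {
        need <- need - lens[k]
        starts <- starts[-k]; lens <- lens[-k]
        if (k > 1L) removed_splice <- TRUE
        if (length(lens) == 0L && need >= 0L) {
          if (need > 0L) layout_error("degenerate", "trim exceeds whole layout")
          layout_error("degenerate", "trim consumed whole layout")
        }
      }
    }
  }
  keep <- lens > 0L
  starts <- starts[keep]; lens <- lens[keep]
  if (length(lens) == 0L) layout_error("degenerate", "empty layout")

  structure(list(
    new_pos = starts[1],
    blocks = tibble::tibble(ref_start = starts, length = lens),
    removed_splice = removed_splice,
    hard_clip_added = lead_H + trail_H,
    hard_fill_left = if (!paired) lead_H else 0L,
    hard_fill_right = if (!paired) trail_H else lead_H + trail_H,
    total_query_len = sum(lens)
  ), class = "resolved_layout")
}

#' Rebuild a read sequence from its resolved layout
#'
#' @param layout A `resolved_layout`.
#' @param ref A `genome_reference`.
#' @param contig Contig name.
#' @return Uppercase reference sequence of length `layout$total_query_len`.
#' @export
rebuild_sequence <- function(layout, ref, contig) {
  paste(vapply(seq_len(nrow(layout$blocks)), function(i) {
    s <- layout$blocks$ref_start[i]
    ref_fetch(ref, contig, s, s + layout$blocks$length[i])
  }, character(1)), collapse = "")
}

#' Build the reference-identical CIGAR for a layout
#'
#' Only M (per block) and N (per preserved splice gap) ops remain.
#'
#' @param layout A `resolved_layout`.
#' @return CIGAR string, e.g. `"100M"` or `"50M200N50M"`.
#' @export
build_cigar <- function(layout) {
  b <- layout$blocks
  parts <- paste0(b$length, "M")
  if (nrow(b) > 1L) {
    gaps <- b$ref_start[-1] - (b$ref_start[-nrow(b)] + b$length[-nrow(b)])
    parts <- c(rbind(parts[-length(parts)], paste0(gaps, "N")), parts[length(parts)])
  }
  paste(parts, collapse = "")
}

#' Build the MD tag value for a layout
#'
#' A fully reference-matching read has an MD of its total matched length;
#' splice gaps (N) contribute nothing by the MD convention.
#'
#' @param layout A `resolved_layout`.
#' @return MD string, e.g. `"100"`.
#' @export
build_md <- function(layout) as.character(layout$total_query_len)

#' Rebuild the quality string for a sanitized record
#'
#' Quality values are deliberately passed through unchanged (left out of
#' phase with the rewritten bases rather than edited, which would be a
#' detectable scar); only bases newly materialized from hard clips receive
#' fill qualities on the side where they were added.
#'
#' @param qual Original quality string (`"*"` if unavailable).
#' @param layout A `resolved_layout`.
#' @param options A [sanitize_options()] list.
#' @return Quality string matching the rebuilt sequence length.
#' @export
rebuild_quals <- function(qual, layout, options = sanitize_options()) {
  if (identical(qual, "*")) return("*")
  paste0(strrep(options$hard_clip_qual, layout$hard_fill_left),
         qual,
         strrep(options$hard_clip_qual, layout$hard_fill_right))
}

#' Sanitize one alignment record
#'
#' Rewrites a single record (one-row list as from a record tibble) to pure
#' reference sequence, or signals a discard. Field changes: `seq`, `cigar`,
#' `pos`, `qual` (hard-clip fill only), MD/NM/nM tags, plus the tag policy;
#' all other fields pass through unchanged — in particular TLEN and PNEXT,
#' which the 5'-position rules were designed to keep valid.
#'
#' @param record Named list with the record-tibble fields.
#' @param ref A `genome_reference`.
#' @param options A [sanitize_options()] list.
#' @return A list `list(status = "kept", record = <record>, layout = <layout>)`
#'   or `list(status = "discard", reason = <reason>)` with reason one of
#'   `unmapped`, `secondary`, `supplementary`, `out_of_range`, `degenerate`.
#' @export
sanitize_record <- function(record, ref, options = sanitize_options()) {
  flag <- record$flag
  if (flag_has(flag, FLAG_UNMAPPED)) {
    if (!options$keep_unmapped) return(list(status = "discard", reason = "unmapped"))
    record$tags <- sanitize_tags(record$tags, strict = options$strict,
                                 final_read_len = nchar(record$seq),
                                 zero_edit_distance = FALSE)
    return(list(status = "kept", record = record, layout = NULL))
  }
  if (flag_has(flag, FLAG_SECONDARY) && !options$keep_secondary) {
    return(list(status = "discard", reason = "secondary"))
  }
  if (flag_has(flag, FLAG_SUPPLEMENTARY) && !options$keep_secondary) {
    return(list(status = "discard", reason = "supplementary"))
  }
  if (!record$rname %in% ref$contigs$name) {
    stop("contig '", record$rname,
         "' present in BAM but absent from the reference", call. = FALSE)
  }

  layout <- tryCatch(
    resolve_layout(record$cigar, record$pos, flag_has(flag, FLAG_PAIRED)),
    bamscrub_layout_error = function(e) e
  )
  if (inherits(layout, "bamscrub_layout_error")) {
    return(list(status = "discard", reason = layout$reason))
  }
  last <- nrow(layout$blocks)
  if (layout$blocks$ref_start[last] + layout$blocks$length[last] >
      ref_length(ref, record$rname)) {
    return(list(status = "discard", reason = "out_of_range"))
  }
  if (record$seq != "*" &&
      layout$total_query_len != nchar(record$seq) + layout$hard_clip_added) {
    stop("CIGAR/SEQ length mismatch for record ", record$qname, call. = FALSE)
  }

  record$seq   <- rebuild_sequence(layout, ref, record$rname)
  record$qual  <- rebuild_quals(record$qual, layout, options)
  record$cigar <- build_cigar(layout)
  record$pos   <- layout$new_pos
  if (tag_has(record$tags, "MD")) {
    record$tags <- tag_set(record$tags, "MD", "Z", build_md(layout))
  }
  record$tags <- sanitize_tags(record$tags, strict = options$strict,
                               final_read_len = layout$total_query_len)
  if (options$strict) record$mapq <- 255L
  list(status = "kept", record = record, layout = layout)
}
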