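#' Read an alignment file into header lines and a record table
#'
#' BAM files are decoded through htslib (Rsamtools); `.sam` text files are
#' read directly. All auxiliary tags are preserved byte-identically.
#'
#' @param path Path to a `.bam` or `.sam` file.
#' @return A list with `header` (character vector of `@`-lines) and `records`
#'   (tibble as from [parse_sam_records()]).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
  } else {
    dest <- tempfile()
    out <- tryCatch(
      Rsamtools::asSam(path, dest, overwrite = TRUE),
      error = function(e) stop("unreadable BAM '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    lines <- readLines(out)
    unlink(out)
  }
  is_hdr <- startsWith(lines, "@")
  list(header = lines[is_hdr], records = parse_sam_records(lines[!is_hdr]))
}

#' Contigs declared in a SAM header
#'
#' @param header Character vector of header lines.
#' @return Tibble with columns `name`, `length`, in header order.
#' @export
header_contigs <- function(header) {
  sq <- header[startsWith(header, "@SQ")]
  name <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  len  <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  tibble::tibble(name = name, length = len)
}

#' Append a program line to a SAM header
#'
#' `@SQ` lines are preserved verbatim; one `@PG` line is appended with a
#' unique ID, the program name and version, and the full invocation. If the
#' header already carries a `@PG` chain, the new line's `PP` field points at
#' the last program in it.
#'
#' @param header Character vector of header lines.
#' @param invocation Command line / call to record in `CL:`.
#' @param program Program name for `ID:`/`PN:`.
#' @return The augmented header.
#' @export
build_output_header <- function(header, invocation,
                                program = "bamscrub") {
  if (!any(startsWith(header, "@SQ"))) {
    stop("header declares no @SQ reference sequences", call. = FALSE)
  }
  pg <- header[startsWith(header, "@PG")]
  ids <- sub(".*\tID:([^\t]+).*", "\\1", pg)
  id <- program
  k <- 1L
  while (id %in% ids) { id <- paste0(program, ".", k); k <- k + 1L }
  line <- paste0("@PG\tID:", id, "\tPN:", program,
                 if (length(ids)) paste0("\tPP:", ids[length(ids)]) else "",
                 "\tVN:", as.character(utils::packageVersion("bamscrub")),
                 "\tCL:", invocation)
  c(header, line)
}

order_records <- function(records, contig_order) {
  order(match(records$rname, contig_order), records$pos,
        records$qname, records$flag, method = "radix")
}

#' Write header + records to SAM or BAM
#'
#' Records are coordinate-sorted with a reproducible key (contig order from
#' the header, position, read name, flag) before writing; BAM output is
#' compressed and indexed through htslib.
#'
#' @param header Character vector of header lines.
#' @param records Record tibble.
#' @param path Output path ending in `.bam` or `.sam`.
#' @param sort Coordinate-sort before writing (default TRUE).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(header, records, path, sort = TRUE) {
  if (sort && nrow(records) > 0) {
    contigs <- header_contigs(header)$name
    records <- records[order_records(records, contigs), ]
    so <- "@HD\tVN:1.6\tSO:coordinate"
    header <- if (any(startsWith(header, "@HD"))) {
      c(so, header[!startsWith(header, "@HD")])
    } else c(so, header)
  }
  lines <- c(header, format_sam_records(records))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    writeLines(lines, path)
    return(invisible(path))
  }
  tmp <- tempfile(fileext = ".sam")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  dest <- sub("\\.bam$", "", path, ignore.case = TRUE)
  Rsamtools::asBam(tmp, dest, overwrite = TRUE, indexDestination = TRUE)
  invisible(path)
}

#' Sanitize a whole alignment file
#'
#' The end-to-end driver: reads a BAM (or SAM), checks that every contig in
#' the header is present in the reference, rewrites each record to pure
#' reference sequence ([sanitize_record()] + the tag policy), appends a `@PG`
#' header line, and writes a coordinate-sorted, indexed output. Repeated runs
#' on the same input produce byte-identical output.
#'
#' @param in_bam Input `.bam`/`.sam` path.
#' @param reference Reference FASTA path or a `genome_reference`.
#' @param out_bam Output `.bam`/`.sam` path.
#' @param options A [sanitize_options()] list.
#' @param sort Coordinate-sort the output (default TRUE).
#' @param quiet Suppress the summary printed to standard error.
#' @return A `scrub_summary` object (counts in/out, discards by reason,
#'   splices removed, positions shifted); see [tidy()]/[glance()].
#' @export
stream_sanitize <- function(in_bam, reference, out_bam,
                            options = sanitize_options(),
                            sort = TRUE, quiet = TRUE) {
  ref <- if (inherits(reference, "genome_reference")) reference
         else load_reference(reference)
  x <- read_alignments(in_bam)
  hc <- header_contigs(x$header)
  missing <- setdiff(hc$name, ref$contigs$name)
  if (length(missing)) {
    stop("BAM header contig(s) absent from the reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  n <- nrow(x$records)
  kept <- vector("list", n)
  reasons <- character(0)
  splices_removed <- 0L
  positions_shifted <- 0L
  j <- 0L
  for (i in seq_len(n)) {
    rec <- record_row(x$records, i)
    res <- sanitize_record(rec, ref, options)
    if (res$status == "kept") {
      j <- j + 1L
      kept[[j]] <- res$record
      if (!is.null(res$layout)) {
        if (res$layout$removed_splice) splices_removed <- splices_removed + 1L
        if (res$record$pos != rec$pos) positions_shifted <- positions_shifted + 1L
      }
    } else {
      reasons <- c(reasons, res$reason)
    }
  }
  out_records <- records_from_list(kept[seq_len(j)])

  invocation <- paste("stream_sanitize", in_bam,
                      if (inherits(reference, "genome_reference")) ref$path
                      else reference,
                      out_bam,
                      if (options$strict) "--strict" else NULL,
                      if (options$keep_secondary) "--keep-secondary" else NULL,
                      if (options$keep_unmapped) "--keep-unmapped" else NULL)
  header <- build_output_header(x$header, invocation)
  write_alignments(header, out_records, out_bam, sort = sort)

  discarded <- if (length(reasons)) {
    tibble::tibble(reason = reasons) %>%
      dplyr::count(.data$reason, name = "n")
  } else tibble::tibble(reason = character(), n = integer())
  summary <- structure(list(
    records_in = n, records_out = j,
    discarded_by_reason = discarded,
    splices_removed = splices_removed,
    positions_shifted = positions_shifted,
    out_bam = out_bam
  ), class = "scrub_summary")
  if (!quiet) {
    writeLines(format_summary_tsv(summary), con = stderr())
  }
  summary
}

record_row <- function(records, i) {
  list(qname = records$qname[i], flag = records$flag[i],
       rname = records$rname[i], pos = records$pos[i],
       mapq = records$mapq[i], cigar = records$cigar[i],
       rnext = records$rnext[i], pnext = records$pnext[i],
       tlen = records$tlen[i], seq = records$seq[i],
       qual = records$qual[i], tags = records$tags[[i]])
}

records_from_list <- function(recs) {
  if (length(recs) == 0) return(parse_sam_records(character()))
  g <- function(f, mode) vapply(recs, `[[`, vector(mode, 1), f)
  tibble::tibble(
    qname = g("qname", "character"), flag = g("flag", "integer"),
    rname = g("rname", "character"), pos = g("pos", "integer"),
    mapq = g("mapq", "integer"), cigar = g("cigar", "character"),
    rnext = g("rnext", "character"), pnext = g("pnext", "integer"),
    tlen = g("tlen", "integer"), seq = g("seq", "character"),
    qual = g("qual", "character"), tags = lapply(recs, `[[`, "tags")
  )
}

format_summary_tsv <- function(x) {
  d <- x$discarded_by_reason
  c(paste("records_in", x$records_in, sep = "\t"),
    paste("records_out", x$records_out, sep = "\t"),
    if (nrow(d) > 0) paste(paste0("discarded_", d$reason), d$n, sep = "\t"),
    paste("splices_removed", x$splices_removed, sep = "\t"),
    paste("positions_shifted", x$positions_shifted, sep = "\t"))
}

#' @export
print.scrub_summary <- function(x, ...) {
  cat("<scrub_summary>\n")
  cat(format_summary_tsv(x), sep = "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy scrub_summary
#' @export
tidy.scrub_summary <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(disposition = "kept", n = x$records_out),
    x$discarded_by_reason %>%
      dplyr::transmute(disposition = paste0("discarded_", .data$reason),
                       n = .data$n)
  )
}

#' @method glance scrub_summary
#' @export
glance.scrub_summary <- function(x, ...) {
  tibble::tibble(
    records_in = x$records_in, records_out = x$records_out,
    discarded = x$records_in - x$records_out,
    splices_removed = x$splices_removed,
    positions_shifted = x$positions_shifted
  )
}

#' @method autoplot scrub_summary
#' @export
autoplot.scrub_summary <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$disposition, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "records",
                  title = "Record disposition after sanitization") +
    ggplot2::theme_minimal()
}
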