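#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom dplyr %>% mutate filter arrange select bind_rows group_by summarise n left_join anti_join distinct if_else
#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# SAM flag bits
FLAG_PAIRED        <- 0x1L
FLAG_PROPER_PAIR   <- 0x2L
FLAG_UNMAPPED      <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE       <- 0x10L
FLAG_MATE_REVERSE  <- 0x20L
FLAG_FIRST         <- 0x40L
FLAG_SECOND        <- 0x80L
FLAG_SECONDARY     <- 0x100L
FLAG_QCFAIL        <- 0x200L
FLAG_DUP           <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' Parse SAM text lines into a tidy record table
#'
#' One row per alignment record. Positions are converted to the 0-based
#' half-open convention used throughout the package (`pos = -1` marks an
#' unavailable position, stored as 0 in SAM text). Auxiliary tags are kept as
#' raw `TAG:TYPE:VALUE` strings in a list-column so that tags the package does
#' not touch round-trip byte-identically.
#'
#' @param lines Character vector of SAM alignment lines (no header lines).
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, `tags`.
#' @export
parse_sam_records <- function(lines) {
  if (length(lines) == 0) {
    return(tibble::tibble(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = integer(), tlen = integer(),
      seq = character(), qual = character(), tags = list()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    stop("malformed SAM record (fewer than 11 fields) at line ",
         which(nf < 11L)[1], call. = FALSE)
  }
  f <- function(i) vapply(parts, `[[`, character(1), i)
  tibble::tibble(
    qname = f(1),
    flag  = as.integer(f(2)),
    rname = f(3),
    pos   = as.integer(f(4)) - 1L,
    mapq  = as.integer(f(5)),
    cigar = f(6),
    rnext = f(7),
    pnext = as.integer(f(8)) - 1L,
    tlen  = as.integer(f(9)),
    seq   = f(10),
    qual  = f(11),
    tags  = lapply(parts, function(p) if (length(p) > 11L) p[12:length(p)] else character())
  )
}

#' Serialize a record table back to SAM text lines
#'
#' Inverse of [parse_sam_records()]; positions are converted back to the
#' 1-based SAM convention.
#'
#' @param records A record tibble.
#' @return Character vector of SAM alignment lines.
#' @export
format_sam_records <- function(records) {
  if (nrow(records) == 0) return(character())
  base <- paste(records$qname, records$flag, records$rname, records$pos + 1L,
                records$mapq, records$cigar, records$rnext, records$pnext + 1L,
                records$tlen, records$seq, records$qual, sep = "\t")
  tagstr <- vapply(records$tags, function(t) {
    if (length(t) == 0) "" else paste0("\t", paste(t, collapse = "\t"))
  }, character(1))
  paste0(base, tagstr)
}

# --- tag helpers (tags are "TAG:TYPE:VALUE" strings) -------------------------

tag_names <- function(tags) substr(tags, 1L, 2L)

tag_get <- function(tags, name) {
  i <- which(tag_names(tags) == name)
  if (length(i) == 0) return(NULL)
  sub("^..:.:", "", tags[[i[1]]])
}

tag_has <- function(tags, name) name %in% tag_names(tags)

tag_set <- function(tags, name, type, value) {
  entry <- paste0(name, ":", type, ":", value)
  i <- which(tag_names(tags) == name)
  if (length(i) == 0) c(tags, entry) else {
    tags[i[1]] <- entry
    tags
  }
}

tag_drop <- function(tags, names) tags[!(tag_names(tags) %in% names)]
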