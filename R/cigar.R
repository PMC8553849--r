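CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")  # ops that consume read bases
REF_OPS   <- c("M", "D", "N", "=", "X")  # ops that consume reference bases

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string, e.g. `"5S95M"`. `"*"` is not accepted here:
#'   records without a CIGAR (unmapped) are handled before layout resolution.
#' @param validate Check structural invariants (S adjacent to the ends,
#'   optionally outside H; H only at the extreme ends; positive lengths).
#' @return A tibble with columns `op` (character) and `len` (integer).
#' @export
parse_cigar <- function(cigar, validate = TRUE) {
  if (is.na(cigar) || cigar == "" || cigar == "*") {
    stop("record has no CIGAR", call. = FALSE)
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  if (paste(toks, collapse = "") != cigar) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  op  <- substring(toks, nchar(toks))
  len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  if (validate) {
    bad <- setdiff(op, CIGAR_OPS)
    if (length(bad)) stop("unknown CIGAR op '", bad[1], "' in ", cigar, call. = FALSE)
    if (any(len < 1L)) stop("non-positive CIGAR length in ", cigar, call. = FALSE)
    validate_clip_placement(op, cigar)
  }
  tibble::tibble(op = op, len = len)
}

# H only at the extreme ends; S only adjacent to the ends, optionally with H
# outside it.
validate_clip_placement <- function(op, cigar) {
  n <- length(op)
  h <- which(op == "H")
  if (length(h) && !all(h %in% c(1L, n))) {
    stop("H not at the extreme ends in CIGAR ", cigar, call. = FALSE)
  }
  s <- which(op == "S")
  for (i in s) {
    left_end  <- all(op[seq_len(i - 1L)] == "H")
    right_end <- i == n || all(op[seq((i + 1L), n)] == "H")
    if (!(left_end || right_end)) {
      stop("S not adjacent to the ends in CIGAR ", cigar, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Serialize CIGAR ops back to a string
#' @param ops A tibble with columns `op`, `len` (as from [parse_cigar()]).
#' @return CIGAR string.
#' @export
cigar_string <- function(ops) paste0(ops$len, ops$op, collapse = "")

#' Read bases consumed by a CIGAR
#' @param ops Parsed CIGAR tibble.
#' @return Integer number of stored-sequence bases the CIGAR accounts for.
#' @export
cigar_query_length <- function(ops) sum(ops$len[ops$op %in% QUERY_OPS])
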