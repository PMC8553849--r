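# Auxiliary-field sanitization policy. After the sequence itself is reverted
# to reference, the surrounding fields must not betray that variation was ever
# there: edit distances are zeroed, alignment-description tags dropped, and in
# strict mode score/mapping-quality style fields are normalized too. Tags
# outside these sets (cell barcodes, UMIs, gene assignments, read groups,
# custom flags) are preserved byte-identically.

ZERO_TAGS          <- c("NM", "nM")
DROP_TAGS_DEFAULT  <- c("MC", "XN", "XM", "XO", "XG")
STRICT_LEN_TAGS    <- c("AS", "MQ")  # set to read length (only if present)
STRICT_DROP_TAGS   <- c("HI", "IH", "H1", "H2", "OA", "OC", "OP", "OQ",
                        "SA", "SM", "XA", "XS")

#' The tag-sanitization policy as a table
#'
#' @return A tibble with columns `tag`, `action`, `mode` describing what
#'   happens to each named auxiliary tag in default and strict mode.
#' @export
tag_policy <- function() {
  dplyr::bind_rows(
    tibble::tibble(tag = ZERO_TAGS, action = "set to 0", mode = "default"),
    tibble::tibble(tag = DROP_TAGS_DEFAULT, action = "drop", mode = "default"),
    tibble::tibble(tag = STRICT_LEN_TAGS, action = "set to read length",
                   mode = "strict"),
    tibble::tibble(tag = "NH", action = "set to 1", mode = "strict"),
    tibble::tibble(tag = STRICT_DROP_TAGS, action = "drop", mode = "strict")
  )
}

# Core tag rewrite on a raw tag vector. zero_edit_distance = FALSE is used for
# pass-through unmapped records, which have no alignment whose edit distance
# could meaningfully be zeroed.
sanitize_tags <- function(tags, strict, final_read_len,
                          zero_edit_distance = TRUE) {
  if (zero_edit_distance) {
    for (t in ZERO_TAGS) {
      if (tag_has(tags, t)) tags <- tag_set(tags, t, "i", 0L)
    }
  }
  tags <- tag_drop(tags, DROP_TAGS_DEFAULT)
  if (strict) {
    for (t in STRICT_LEN_TAGS) {
      if (tag_has(tags, t)) tags <- tag_set(tags, t, "i", final_read_len)
    }
    if (tag_has(tags, "NH")) tags <- tag_set(tags, "NH", "i", 1L)
    tags <- tag_drop(tags, STRICT_DROP_TAGS)
  }
  tags
}

#' Apply the auxiliary-tag policy to a record
#'
#' Default mode: NM/nM (edit distance) are zeroed where present; the
#' alignment-description tags MC, XN, XM, XO, XG are dropped. Strict mode
#' additionally sets MAPQ to 255, AS/MQ to the read length and NH to 1 (each
#' only where already present — adding an absent tag would itself be a
#' detectable scar) and drops HI, IH, H1, H2, OA, OC, OP, OQ, SA, SM, XA, XS.
#' Every other tag is preserved byte-identically. The policy is idempotent.
#'
#' @param record Named list with record-tibble fields (at least `tags`,
#'   `mapq`).
#' @param strict Apply the strict-mode extras?
#' @param final_read_len Read length after sanitization (for AS/MQ).
#' @return The record with `tags` (and in strict mode `mapq`) rewritten.
#' @export
apply_tag_policy <- function(record, strict = FALSE, final_read_len) {
  record$tags <- sanitize_tags(record$tags, strict = strict,
                               final_read_len = final_read_len)
  if (strict) record$mapq <- 255L
  record
}
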