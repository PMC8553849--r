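# Brute-force per-base layout oracle: expands the CIGAR one base at a time
# into the vector of reference positions the rewritten read will cover, then
# applies clip/extension/trim rules on that vector. Shares no code with
# resolve_layout (which works on run-length blocks).
oracle_layout <- function(cigar, pos, paired) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  ops <- substring(toks, nchar(toks))
  lens <- as.integer(substring(toks, 1, nchar(toks) - 1))
  chars <- rep(ops, lens)

  n <- length(chars)
  lead <- 0L
  while (lead < n && chars[lead + 1] %in% c("S", "H")) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && chars[n - trail] %in% c("S", "H")) trail <- trail + 1L
  core <- if (n - lead - trail > 0) chars[seq(lead + 1L, n - trail)] else character()

  cov <- integer()
  cur <- pos
  ext <- 0L; trim <- 0L
  for (ch in core) {
    if (ch %in% c("M", "=", "X")) { cov <- c(cov, cur); cur <- cur + 1L }
    else if (ch == "D") { cov <- c(cov, cur); cur <- cur + 1L; trim <- trim + 1L }
    else if (ch == "I") ext <- ext + 1L
    else if (ch == "N") cur <- cur + 1L
    # P consumes nothing
  }
  if (lead > 0L) {
    if (!paired) {
      if (pos - lead < 0) stop("oracle:out_of_range")
      cov <- c(seq(pos - lead, pos - 1L), cov)
    } else ext <- ext + lead
  }
  ext <- ext + trail

  gaps_before <- sum(diff(cov) != 1L)
  net <- ext - trim
  if (net > 0L) {
    cov <- c(cov, seq(cov[length(cov)] + 1L, length.out = net))
  } else if (net < 0L) {
    if (length(cov) + net <= 0L) stop("oracle:degenerate")
    cov <- cov[seq_len(length(cov) + net)]
  }
  run_id <- cumsum(c(1L, diff(cov) != 1L))
  blocks <- tibble::tibble(
    ref_start = as.integer(tapply(cov, run_id, min)),
    length = as.integer(tapply(cov, run_id, length))
  )
  list(new_pos = cov[1], blocks = blocks,
       removed_splice = sum(diff(cov) != 1L) < gaps_before,
       total_query_len = length(cov))
}

# Random aligner-plausible CIGAR: optional hard/soft leading clip, a core of
# alternating M / {I,D,N} runs starting and ending in M, optional trailing
# clip.
rand_cigar <- function() {
  piece <- function(op, lo = 1, hi = 15) paste0(sample(lo:hi, 1), op)
  out <- character()
  if (runif(1) < 0.15) out <- c(out, piece("H", 1, 8))
  if (runif(1) < 0.3) out <- c(out, piece("S", 1, 10))
  k <- sample(1:4, 1)
  for (i in seq_len(k)) {
    out <- c(out, piece("M", 2, 30))
    if (i < k) out <- c(out, piece(sample(c("I", "D", "N", "N"), 1), 1, 25))
  }
  if (runif(1) < 0.3) out <- c(out, piece("S", 1, 10))
  if (runif(1) < 0.15) out <- c(out, piece("H", 1, 8))
  paste(out, collapse = "")
}

layout_or_reason <- function(expr) {
  tryCatch(expr,
           bamscrub_layout_error = function(e) paste0("err:", e$reason),
           error = function(e) {
             if (grepl("oracle:", conditionMessage(e))) {
               paste0("err:", sub(".*oracle:", "", conditionMessage(e)))
             } else stop(e)
           })
}
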