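#' Simulation parameters for synthetic fixtures
#'
#' Defines the study conditions for the synthetic reference + donor + reads
#' fixtures: a random genome, a donor haplotype carrying planted SNPs and
#' short indels, and aligner-faithful reads covering every rewrite case
#' (mismatches, insertions, deletions, soft/hard clips, spliced alignments,
#' paired ends, unmapped and secondary records).
#'
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @param n_contigs,contig_len Number of contigs and length of each (bp).
#' @param n_snps,n_insertions,n_deletions Planted variant counts.
#' @param read_len Read length (bp; default 100).
#' @param n_reads Total number of records to emit (including unmapped and
#'   secondary records at the requested fractions).
#' @param paired Generate proper read pairs (default TRUE).
#' @param fraction_spliced Fraction of mapped reads spanning one intron.
#' @param fraction_clipped Fraction of mapped reads given an adapter-style
#'   soft or hard clip at one end.
#' @param clip_len Range (min, max) of adapter clip lengths.
#' @param indel_len Range (min, max) of planted indel lengths (1-10 bp).
#' @param intron_len Range (min, max) of simulated intron lengths.
#' @param fraction_unmapped,fraction_secondary Fractions of unmapped and
#'   secondary records among `n_reads`.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(seed = 1L, n_contigs = 1L, contig_len = 100000L,
                       n_snps = 60L, n_insertions = 20L, n_deletions = 20L,
                       read_len = 100L, n_reads = 2000L, paired = TRUE,
                       fraction_spliced = 0.15, fraction_clipped = 0.10,
                       clip_len = c(4L, 12L), indel_len = c(1L, 10L),
                       intron_len = c(60L, 300L),
                       fraction_unmapped = 0.01, fraction_secondary = 0.01) {
  p <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
            contig_len = as.integer(contig_len), n_snps = as.integer(n_snps),
            n_insertions = as.integer(n_insertions),
            n_deletions = as.integer(n_deletions),
            read_len = as.integer(read_len), n_reads = as.integer(n_reads),
            paired = isTRUE(paired),
            fraction_spliced = fraction_spliced,
            fraction_clipped = fraction_clipped,
            clip_len = as.integer(clip_len), indel_len = as.integer(indel_len),
            intron_len = as.integer(intron_len),
            fraction_unmapped = fraction_unmapped,
            fraction_secondary = fraction_secondary)
  fr <- c(p$fraction_spliced, p$fraction_clipped, p$fraction_unmapped,
          p$fraction_secondary)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (p$contig_len <= 0) stop("contig_len must be positive", call. = FALSE)
  if (any(c(p$n_contigs, p$n_snps, p$n_insertions, p$n_deletions,
            p$n_reads) < 0) || p$read_len <= 0) {
    stop("counts must be non-negative and read_len positive", call. = FALSE)
  }
  if (any(p$indel_len < 1L) || any(p$indel_len > 10L)) {
    stop("indel_len must lie in 1-10 bp", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random reference genome
#'
#' I.i.d.-uniform A/C/G/T sequence per contig, written to FASTA (with `.fai`)
#' and loaded as a `genome_reference`. Fully reproducible from `params$seed`.
#'
#' @param params A [sim_params()] list.
#' @param fasta Output FASTA path.
#' @return A `genome_reference`.
#' @export
generate_reference <- function(params, fasta = tempfile(fileext = ".fa")) {
  set.seed(params$seed)
  seqs <- stats::setNames(
    vapply(seq_len(params$n_contigs), function(i) rand_bases(params$contig_len),
           character(1)),
    paste0("chrS", seq_len(params$n_contigs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta, width = 70L)
  load_reference(fasta)
}

#' Plant donor variants into a reference
#'
#' Places the requested numbers of SNPs and 1-10 bp insertions/deletions at
#' positions spaced at least `2 * read_len` apart, and applies them to build
#' the donor haplotype. Variants are recorded VCF-style: `pos` is the 0-based
#' anchor base, `ref` the reference allele and `alt` the donor allele at the
#' anchor (for a deletion, `ref` spans the deleted bases).
#'
#' @param ref A `genome_reference`.
#' @param params A [sim_params()] list.
#' @return A list with `donor` (named character vector of donor contig
#'   sequences) and `variants` (tibble `id`, `contig`, `pos`, `ref`, `alt`,
#'   `kind`, `len`).
#' @export
plant_variants <- function(ref, params) {
  set.seed(params$seed + 1L)
  n_var <- params$n_snps + params$n_insertions + params$n_deletions
  spacing <- 2L * params$read_len + 40L
  margin_hi <- params$read_len + max(params$intron_len) + 60L
  slots <- dplyr::bind_rows(lapply(seq_len(nrow(ref$contigs)), function(i) {
    L <- ref$contigs$length[i]
    lo <- params$read_len
    hi <- L - margin_hi
    if (hi <= lo) return(tibble::tibble(contig = character(), slot = integer()))
    tibble::tibble(contig = ref$contigs$name[i],
                   slot = seq.int(lo, hi, by = spacing))
  }))
  if (nrow(slots) < n_var) {
    stop("infeasible variant density: ", n_var, " variants need ", n_var,
         " slots at ", spacing, " bp spacing, only ", nrow(slots),
         " available", call. = FALSE)
  }
  pick <- slots[sort(sample.int(nrow(slots), n_var)), ]
  pick$pos <- pick$slot + sample.int(40L, n_var, replace = TRUE) - 1L
  kind <- sample(c(rep("SNP", params$n_snps),
                   rep("insertion", params$n_insertions),
                   rep("deletion", params$n_deletions)))
  empty <- tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          kind = character(), len = integer())
  v <- purrr::map_dfr(seq_len(n_var), function(i) {
    ct <- pick$contig[i]; p <- pick$pos[i]; k <- kind[i]
    anchor <- ref_fetch(ref, ct, p, p + 1L)
    if (k == "SNP") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1L)
      tibble::tibble(contig = ct, pos = p, ref = anchor, alt = alt,
                     kind = k, len = 1L)
    } else if (k == "insertion") {
      l <- sample(seq(params$indel_len[1], params$indel_len[2]), 1L)
      tibble::tibble(contig = ct, pos = p, ref = anchor,
                     alt = paste0(anchor, rand_bases(l)), kind = k, len = l)
    } else {
      l <- sample(seq(params$indel_len[1], params$indel_len[2]), 1L)
      tibble::tibble(contig = ct, pos = p,
                     ref = ref_fetch(ref, ct, p, p + 1L + l),
                     alt = anchor, kind = k, len = l)
    }
  })
  if (n_var == 0L) v <- empty
  v <- v[order(match(v$contig, ref$contigs$name), v$pos), ]
  v$id <- seq_len(nrow(v))
  v <- v[, c("id", "contig", "pos", "ref", "alt", "kind", "len")]

  donor <- ref$seq
  for (ct in unique(v$contig)) {
    s <- donor[[ct]]
    vv <- v[v$contig == ct, ]
    for (i in rev(seq_len(nrow(vv)))) {   # right to left: positions stay valid
      p <- vv$pos[i]
      if (vv$kind[i] == "SNP") {
        substr(s, p + 1L, p + 1L) <- vv$alt[i]
      } else if (vv$kind[i] == "insertion") {
        s <- paste0(substr(s, 1L, p + 1L), substr(vv$alt[i], 2L, nchar(vv$alt[i])),
                    substr(s, p + 2L, nchar(s)))
      } else {
        s <- paste0(substr(s, 1L, p + 1L), substr(s, p + 2L + vv$len[i], nchar(s)))
      }
    }
    donor[[ct]] <- s
  }
  list(donor = donor, variants = v)
}

# --- read construction -------------------------------------------------------

# Walk the reference from position s, consuming read_len query bases and
# expressing every planted variant in the window as the aligner would encode
# it (SNP -> mismatching M base, insertion -> I, deletion -> D), optionally
# inserting one N intron at query offset jq. Returns parallel op/len/chunk
# vectors plus per-op variant ids.
walk_read <- function(ref, contig, s, read_len, vtab, jq = NA, intron = 0L) {
  op <- character(); len <- integer(); chunk <- character(); vid <- integer()
  push <- function(o, l, ch, id = NA_integer_) {
    op <<- c(op, o); len <<- c(len, as.integer(l))
    chunk <<- c(chunk, ch); vid <<- c(vid, id)
  }
  q <- 0L; cur <- as.integer(s)
  vp <- 1L; nv <- nrow(vtab)
  while (q < read_len) {
    d_splice <- if (!is.na(jq)) jq - q else Inf
    if (d_splice <= 0) {
      push("N", intron, "")
      cur <- cur + intron
      jq <- NA
      next
    }
    while (vp <= nv && vtab$pos[vp] < cur) vp <- vp + 1L
    has_v <- vp <= nv
    d_var <- if (!has_v) Inf
             else if (vtab$kind[vp] == "SNP") vtab$pos[vp] - cur
             else vtab$pos[vp] - cur + 1L
    if (has_v && d_var == 0 && vtab$kind[vp] == "SNP") {
      push("M", 1L, vtab$alt[vp], vtab$id[vp])
      q <- q + 1L; cur <- cur + 1L; vp <- vp + 1L
      next
    }
    step <- min(read_len - q, d_splice, d_var)
    if (step > 0) {
      push("M", step, ref_fetch(ref, contig, cur, cur + step))
      q <- q + step; cur <- cur + step
    }
    if (q >= read_len) break
    if (has_v && d_var == step && d_var <= d_splice && vtab$kind[vp] != "SNP") {
      if (vtab$kind[vp] == "insertion") {
        ins <- substr(vtab$alt[vp], 2L, nchar(vtab$alt[vp]))
        il <- min(nchar(ins), read_len - q)
        push("I", il, substr(ins, 1L, il), vtab$id[vp])
        q <- q + il
      } else {
        push("D", vtab$len[vp], "", vtab$id[vp])
        cur <- cur + vtab$len[vp]
      }
      vp <- vp + 1L
    }
  }
  list(op = op, len = len, chunk = chunk, vid = vid, pos = as.integer(s))
}

# Aligner-style end clipping: an indel op whose breakpoint sits closer than
# 5 bp to a read end is not emitted as I/D; the end is soft-clipped instead
# (the clipped bases still carry the donor alleles).
clip_indel_ends <- function(w, read_len) {
  repeat {
    qoff <- cumsum(c(0L, ifelse(w$op %in% QUERY_OPS, w$len, 0L)))
    idx <- which(w$op %in% c("I", "D") )
    hit <- NULL
    for (i in idx) {
      q0 <- qoff[i]; q1 <- qoff[i + 1L]
      if (q0 < 5L) { hit <- list(i = i, side = "left"); break }
      if (read_len - q1 < 5L) { hit <- list(i = i, side = "right"); break }
    }
    if (is.null(hit)) return(w)
    i <- hit$i
    if (hit$side == "left") {
      keep <- seq_along(w$op) > i
      cliplen <- qoff[i + 1L]
      clipseq <- paste(w$chunk[seq_len(i)], collapse = "")
      ref_consumed <- sum(w$len[seq_len(i)][w$op[seq_len(i)] %in% REF_OPS])
      w <- list(op = c("S", w$op[keep]), len = c(cliplen, w$len[keep]),
                chunk = c(clipseq, w$chunk[keep]),
                vid = c(w$vid[i], w$vid[keep]),
                pos = w$pos + ref_consumed)
    } else {
      keep <- seq_along(w$op) < i
      cliplen <- read_len - qoff[i]
      clipseq <- paste(w$chunk[seq(i, length(w$op))], collapse = "")
      w <- list(op = c(w$op[keep], "S"), len = c(w$len[keep], cliplen),
                chunk = c(w$chunk[keep], clipseq),
                vid = c(w$vid[keep], w$vid[i]),
                pos = w$pos)
    }
  }
}

# Optional adapter-style clip at one end of a variant-free terminal M run.
adapter_clip <- function(w, clip_len_range, read_len) {
  k <- sample(seq(clip_len_range[1], clip_len_range[2]), 1L)
  hard <- stats::runif(1) < 0.5
  side <- if (stats::runif(1) < 0.5) "left" else "right"
  i <- if (side == "left") 1L else length(w$op)
  if (w$op[i] != "M" || w$len[i] < k + 10L || !is.na(w$vid[i])) return(w)
  if (side == "left") {
    w$len[1] <- w$len[1] - k
    w$chunk[1] <- substr(w$chunk[1], k + 1L, nchar(w$chunk[1]))
    w$pos <- w$pos + k
    w <- list(op = c(if (hard) "H" else "S", w$op),
              len = c(k, w$len),
              chunk = c(if (hard) "" else rand_bases(k), w$chunk),
              vid = c(NA_integer_, w$vid), pos = w$pos)
  } else {
    n <- length(w$op)
    w$len[n] <- w$len[n] - k
    w$chunk[n] <- substr(w$chunk[n], 1L, w$len[n])
    w <- list(op = c(w$op, if (hard) "H" else "S"),
              len = c(w$len, k),
              chunk = c(w$chunk, if (hard) "" else rand_bases(k)),
              vid = c(w$vid, NA_integer_), pos = w$pos)
  }
  w
}

merge_ops <- function(w) {
  if (length(w$op) <= 1L) return(w)
  grp <- cumsum(c(TRUE, w$op[-1] != w$op[-length(w$op)]))
  idx <- unname(split(seq_along(w$op), factor(grp, levels = unique(grp))))
  list(op = vapply(idx, function(i) w$op[i[1]], character(1)),
       len = vapply(idx, function(i) sum(w$len[i]), integer(1)),
       chunk = vapply(idx, function(i) paste(w$chunk[i], collapse = ""),
                      character(1)),
       vid = vapply(idx, function(i) {
         v <- w$vid[i]; v <- v[!is.na(v)]
         if (length(v)) v[1] else NA_integer_
       }, integer(1)),
       pos = w$pos)
}

# MD and NM for an op walk against the reference. MD counts matched bases,
# names mismatched reference bases, and prefixes deletions with '^'; counts
# continue across I and N, which MD does not represent.
md_nm <- function(w, ref, contig) {
  md <- character(); run <- 0L; nm <- 0L
  cur <- w$pos
  for (i in seq_along(w$op)) {
    o <- w$op[i]; l <- w$len[i]
    if (o == "M") {
      refch <- ref_fetch(ref, contig, cur, cur + l)
      if (identical(refch, w$chunk[i])) {
        run <- run + l
      } else {
        a <- strsplit(w$chunk[i], "")[[1]]
        b <- strsplit(refch, "")[[1]]
        for (j in seq_len(l)) {
          if (a[j] == b[j]) run <- run + 1L
          else {
            md <- c(md, as.character(run), b[j]); run <- 0L; nm <- nm + 1L
          }
        }
      }
      cur <- cur + l
    } else if (o == "D") {
      md <- c(md, as.character(run), "^", ref_fetch(ref, contig, cur, cur + l))
      run <- 0L
      nm <- nm + l
      cur <- cur + l
    } else if (o == "N") {
      cur <- cur + l
    } else if (o == "I") {
      nm <- nm + l
    }
  }
  list(md = paste(c(md, as.character(run)), collapse = ""), nm = nm)
}

rand_quals <- function(n) {
  paste(sample(strsplit("FFFFFJJJAA:,", "")[[1]], n, replace = TRUE),
        collapse = "")
}

finalize_mapped <- function(w, ref, contig, qname, flag, params, barcode, umi) {
  w <- merge_ops(w)
  seqs <- paste(w$chunk[w$op %in% QUERY_OPS], collapse = "")
  e <- md_nm(w, ref, contig)
  expressed <- w$vid[!is.na(w$vid)]
  clipped_vids <- w$vid[!is.na(w$vid) & w$op %in% c("S", "H")]
  tags <- c(paste0("NM:i:", e$nm), paste0("MD:Z:", e$md),
            paste0("AS:i:", nchar(seqs) - 2L * e$nm), "NH:i:1",
            paste0("CB:Z:", barcode), paste0("UB:Z:", umi))
  if (any(w$op == "N")) tags <- c(tags, "XS:A:+")
  list(record = list(qname = qname, flag = flag, rname = contig, pos = w$pos,
                     mapq = 60L, cigar = cigar_string(tibble::tibble(op = w$op, len = w$len)),
                     rnext = "*", pnext = -1L, tlen = 0L,
                     seq = seqs, qual = rand_quals(nchar(seqs)), tags = tags),
       ref_end = w$pos + sum(w$len[w$op %in% REF_OPS]),
       expressed = setdiff(expressed, clipped_vids),
       clipped = clipped_vids)
}

#' Simulate aligned reads over a donor haplotype
#'
#' Samples read windows uniformly along the genome and encodes every planted
#' variant the window covers exactly as an aligner would (mismatching M base,
#' I, D; indel breakpoints closer than 5 bp to a read end become soft clips;
#' a configurable fraction of reads gains an adapter-style clip, one intron,
#' a mate, or is emitted unmapped/secondary). MD and NM are computed against
#' the reference. Writes a coordinate-sorted, indexed BAM plus a ground-truth
#' TSV.
#'
#' @param ref A `genome_reference`.
#' @param donor Donor haplotype (from [plant_variants()]); carried for
#'   interface completeness — reads are built from the variant table, whose
#'   consistency with `donor` is asserted.
#' @param variants Truth-variant tibble from [plant_variants()].
#' @param params A [sim_params()] list.
#' @param bam Output BAM path.
#' @param truth_tsv Output truth table path (columns contig, pos (1-based),
#'   ref, alt, kind).
#' @return A list: `records` (record tibble), `expressed` (tibble `qname`,
#'   `id`, `mode` saying which variant each read carries, aligned or
#'   clipped), `bam`, `truth_tsv`.
#' @export
simulate_alignments <- function(ref, donor, variants, params,
                                bam = tempfile(fileext = ".bam"),
                                truth_tsv = tempfile(fileext = ".tsv")) {
  set.seed(params$seed + 2L)
  n <- params$n_reads
  n_unmapped <- round(params$fraction_unmapped * n)
  n_secondary <- round(params$fraction_secondary * n)
  n_mapped <- n - n_unmapped - n_secondary
  if (params$paired) n_mapped <- n_mapped - n_mapped %% 2L
  rl <- params$read_len
  margin <- rl + max(params$intron_len) + 60L

  recs <- list(); expr <- list(); ri <- 0L
  add <- function(rec) { ri <<- ri + 1L; recs[[ri]] <<- rec }
  note_expr <- function(qname, ids, mode) {
    if (length(ids)) {
      expr[[length(expr) + 1L]] <<-
        tibble::tibble(qname = qname, id = ids, mode = mode)
    }
  }

  make_one <- function(contig, qname, flag, s = NULL) {
    L <- ref_length(ref, contig)
    if (is.null(s)) s <- sample.int(L - margin, 1L) - 1L
    s <- min(s, L - margin - 1L)
    vtab <- variants[variants$contig == contig, ]
    # do not start inside a deleted span: those donor bases do not exist
    inside <- which(vtab$kind == "deletion" & vtab$pos < s &
                      s <= vtab$pos + vtab$len)
    if (length(inside)) s <- vtab$pos[inside[1]] + vtab$len[inside[1]] + 1L
    spliced <- stats::runif(1) < params$fraction_spliced
    jq <- if (spliced) sample(15:(rl - 15L), 1L) else NA
    intron <- if (spliced) sample(seq(params$intron_len[1], params$intron_len[2]), 1L) else 0L
    w <- walk_read(ref, contig, s, rl, vtab, jq, intron)
    w <- clip_indel_ends(w, rl)
    if (stats::runif(1) < params$fraction_clipped) {
      w <- adapter_clip(w, params$clip_len, rl)
    }
    f <- finalize_mapped(w, ref, contig, qname, flag, params,
                         barcode = paste0("BC", rand_bases(8)),
                         umi = rand_bases(10))
    note_expr(qname, f$expressed, "aligned")
    note_expr(qname, f$clipped, "clipped")
    f$start <- s
    f
  }

  contigs <- ref$contigs$name
  wts <- ref$contigs$length / sum(ref$contigs$length)
  k <- 0L
  if (params$paired) {
    for (i in seq_len(n_mapped / 2L)) {
      k <- k + 1L
      qname <- sprintf("sim%06d", k)
      ct <- sample(contigs, 1L, prob = wts)
      f1 <- make_one(ct, qname, flag = 0x1L + 0x2L + 0x20L + 0x40L)
      f2 <- make_one(ct, qname, flag = 0x1L + 0x2L + 0x10L + 0x80L,
                     s = f1$start + sample(120:350, 1L))
      r1 <- f1$record; r2 <- f2$record
      left <- min(r1$pos, r2$pos)
      right <- max(f1$ref_end, f2$ref_end)
      tl <- right - left
      r1$rnext <- "="; r2$rnext <- "="
      r1$pnext <- r2$pos; r2$pnext <- r1$pos
      r1$tlen <- if (r1$pos <= r2$pos) tl else -tl
      r2$tlen <- -r1$tlen
      r1$tags <- c(r1$tags, paste0("MC:Z:", r2$cigar))
      r2$tags <- c(r2$tags, paste0("MC:Z:", r1$cigar))
      add(r1); add(r2)
    }
  } else {
    for (i in seq_len(n_mapped)) {
      k <- k + 1L
      qname <- sprintf("sim%06d", k)
      ct <- sample(contigs, 1L, prob = wts)
      add(make_one(ct, qname, flag = 0L)$record)
    }
  }
  # secondary: re-emit an existing mapped record at the same coordinates
  if (n_secondary > 0L && ri > 0L) {
    src <- sample.int(ri, n_secondary, replace = n_secondary > ri)
    for (i in src) {
      r <- recs[[i]]
      r$flag <- bitwOr(r$flag, FLAG_SECONDARY)
      r$mapq <- 3L
      add(r)
    }
  }
  for (i in seq_len(n_unmapped)) {
    k <- k + 1L
    add(list(qname = sprintf("sim%06d", k), flag = FLAG_UNMAPPED, rname = "*",
             pos = -1L, mapq = 0L, cigar = "*", rnext = "*", pnext = -1L,
             tlen = 0L, seq = rand_bases(rl), qual = rand_quals(rl),
             tags = c(paste0("CB:Z:BC", rand_bases(8)),
                      paste0("UB:Z:", rand_bases(10)))))
  }

  records <- records_from_list(recs[seq_len(ri)])
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", ref$contigs$name, "\tLN:", ref$contigs$length),
              "@PG\tID:bamscrub-sim\tPN:bamscrub-sim")
  write_alignments(header, records, bam, sort = TRUE)
  readr::write_tsv(
    dplyr::transmute(variants, contig = .data$contig, pos = .data$pos + 1L,
                     ref = .data$ref, alt = .data$alt, kind = .data$kind),
    truth_tsv)
  expressed <- if (length(expr)) dplyr::bind_rows(expr) else
    tibble::tibble(qname = character(), id = integer(), mode = character())
  list(records = records, expressed = expressed, bam = bam,
       truth_tsv = truth_tsv)
}

#' Generate a complete synthetic fixture
#'
#' Orchestrates [generate_reference()], [plant_variants()] and
#' [simulate_alignments()] into one seeded, self-consistent fixture on disk:
#' FASTA (+ .fai), coordinate-sorted BAM (+ .bai), ground-truth TSV and a
#' plain-text echo of the parameters.
#'
#' @param params A [sim_params()] list.
#' @param dir Output directory (created if needed).
#' @return A list: `ref`, `donor`, `variants`, `records`, `expressed`, and
#'   the paths `fasta`, `bam`, `truth_tsv`, `params_txt`.
#' @export
simulate_fixture <- function(params = sim_params(), dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fa")
  ref <- generate_reference(params, fasta)
  pv <- plant_variants(ref, params)
  sim <- simulate_alignments(ref, pv$donor, pv$variants, params,
                             bam = file.path(dir, "reads.bam"),
                             truth_tsv = file.path(dir, "truth.tsv"))
  params_txt <- file.path(dir, "params.txt")
  writeLines(paste(names(unclass(params)),
                   vapply(unclass(params), function(x) paste(x, collapse = ","),
                          character(1)),
                   sep = "\t"), params_txt)
  list(ref = ref, donor = pv$donor, variants = pv$variants,
       records = sim$records, expressed = sim$expressed,
       fasta = fasta, bam = sim$bam, truth_tsv = sim$truth_tsv,
       params_txt = params_txt)
}
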