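test_that("fixtures are byte-identical across runs with the same seed", {
  p <- small_sim_params(seed = 5)
  fx1 <- simulate_fixture(p)
  fx2 <- simulate_fixture(p)
  expect_identical(readBin(fx1$bam, "raw", file.size(fx1$bam)),
                   readBin(fx2$bam, "raw", file.size(fx2$bam)))
  expect_identical(readLines(fx1$truth_tsv), readLines(fx2$truth_tsv))
  expect_identical(readLines(fx1$fasta), readLines(fx2$fasta))
  fx3 <- simulate_fixture(small_sim_params(seed = 6))
  expect_false(identical(readLines(fx3$fasta), readLines(fx1$fasta)))
})

test_that("planted variants are consistent with reference and donor", {
  p <- small_sim_params(seed = 8)
  ref <- generate_reference(p)
  pv <- plant_variants(ref, p)
  v <- pv$variants
  expect_equal(nrow(v), p$n_snps + p$n_insertions + p$n_deletions)
  for (i in seq_len(nrow(v))) {
    expect_identical(ref_fetch(ref, v$contig[i], v$pos[i],
                               v$pos[i] + nchar(v$ref[i])), v$ref[i])
    expect_false(v$ref[i] == v$alt[i])
  }
  # minimum spacing >= 2 * read_len
  by_ct <- split(v$pos, v$contig)
  expect_true(all(unlist(lapply(by_ct, function(x) diff(sort(x)))) >=
                    2L * p$read_len))
  # donor length bookkeeping
  dlen <- sum(nchar(pv$donor))
  rlen <- sum(ref$contigs$length)
  expect_equal(dlen, rlen + sum(v$len[v$kind == "insertion"]) -
                 sum(v$len[v$kind == "deletion"]))
  # donor reproduces alt alleles exactly at lifted coordinates
  shift <- 0L
  vv <- v[order(v$pos), ]
  for (i in seq_len(nrow(vv))) {
    got <- substr(pv$donor[[vv$contig[i]]], vv$pos[i] + 1L + shift,
                  vv$pos[i] + nchar(vv$alt[i]) + shift)
    expect_identical(got, vv$alt[i])
    shift <- shift + nchar(vv$alt[i]) - nchar(vv$ref[i])
  }
  # zero variants: donor is the reference
  p0 <- small_sim_params(seed = 8, n_snps = 0, n_insertions = 0,
                         n_deletions = 0)
  pv0 <- plant_variants(ref, p0)
  expect_identical(pv0$donor, ref$seq)
  expect_equal(nrow(pv0$variants), 0L)
})

test_that("infeasible variant density is refused", {
  p <- sim_params(seed = 1, contig_len = 2000L, n_snps = 50L)
  ref <- generate_reference(p)
  expect_error(plant_variants(ref, p), "infeasible")
})

test_that("simulated MD and NM agree with samtools calmd", {
  skip_if(Sys.which("samtools") == "", "samtools not on PATH")
  fx <- simulate_fixture(small_sim_params(seed = 31))
  out <- system2("samtools", c("calmd", fx$bam, fx$fasta),
                 stdout = TRUE, stderr = FALSE)
  got <- parse_sam_records(out[!startsWith(out, "@")])
  ours <- fx$records
  key <- function(r) paste(r$qname, r$flag)
  m <- match(key(ours), key(got))
  expect_false(anyNA(m))
  for (i in seq_len(nrow(ours))) {
    if (bamscrub:::flag_has(ours$flag[i], 4L)) next
    expect_identical(bamscrub:::tag_get(ours$tags[[i]], "MD"),
                     bamscrub:::tag_get(got$tags[[m[i]]], "MD"),
                     label = paste("MD for", ours$qname[i]))
    expect_identical(bamscrub:::tag_get(ours$tags[[i]], "NM"),
                     bamscrub:::tag_get(got$tags[[m[i]]], "NM"),
                     label = paste("NM for", ours$qname[i]))
  }
})

test_that("requested read shapes are realized", {
  fx <- simulate_fixture(sim_params(seed = 41, contig_len = 50000L,
                                    n_reads = 400L, n_snps = 20L,
                                    n_insertions = 8L, n_deletions = 8L))
  r <- fx$records
  expect_true(any(grepl("N", r$cigar, fixed = TRUE)))
  expect_true(any(grepl("S", r$cigar, fixed = TRUE) |
                    grepl("H", r$cigar, fixed = TRUE)))
  expect_true(any(grepl("I", r$cigar, fixed = TRUE)))
  expect_true(any(grepl("D", r$cigar, fixed = TRUE)))
  expect_true(any(bamscrub:::flag_has(r$flag, 4L)))     # unmapped
  expect_true(any(bamscrub:::flag_has(r$flag, 256L)))   # secondary
  expect_true(any(bamscrub:::flag_has(r$flag, 1L)))     # paired
  # mate fields consistent within pairs
  pr <- r[bamscrub:::flag_has(r$flag, 1L), ]
  pr1 <- pr[bamscrub:::flag_has(pr$flag, 64L), ]
  pr2 <- pr[bamscrub:::flag_has(pr$flag, 128L), ]
  m <- match(pr1$qname, pr2$qname)
  expect_false(anyNA(m))
  expect_equal(pr1$pnext, pr2$pos[m])
  expect_equal(pr1$tlen, -pr2$tlen[m])
})

test_that("pileup of the raw fixture recovers exactly the aligned-form
           variant positions", {
  fx <- simulate_fixture(small_sim_params(seed = 51))
  raw <- residual_audit(fx$bam, fx$ref)
  got_pos <- sort(unique(raw$residual$pos))
  exp_ids <- unique(fx$expressed$id[fx$expressed$mode == "aligned"])
  v <- fx$variants
  expected <- integer()
  for (i in exp_ids) {
    vi <- v[v$id == i, ]
    expected <- c(expected,
                  switch(vi$kind,
                         SNP = vi$pos,
                         insertion = vi$pos,             # '+' anchor
                         deletion = seq(vi$pos + 1L, vi$pos + vi$len)))
  }
  # every aligned-form variant leaves a residual footprint, and nothing else
  expect_true(all(got_pos %in% expected))
  covered <- intersect(expected, got_pos)
  expect_setequal(got_pos, covered)
  expect_true(length(got_pos) > 0)
  expect_gt(raw$alt_read_fraction, 0)
})
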