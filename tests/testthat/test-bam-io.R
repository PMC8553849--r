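ten_record_fixture <- function(ref) {
  refseq <- function(s, e) ref_fetch(ref, "chrT", s, e)
  recs <- lapply(1:8, function(i) {
    p <- 10L * i
    make_record(qname = sprintf("m%02d", i), pos = p, cigar = "10M",
                seq = refseq(p, p + 10L), tags = c("NM:i:0", "MD:Z:10"))
  })
  recs <- c(recs,
            list(make_record(qname = "un", flag = 4L, rname = "*", pos = -1L,
                             mapq = 0L, cigar = "*"),
                 make_record(qname = "sec", flag = 256L, pos = 50L,
                             cigar = "10M", seq = refseq(50L, 60L))))
  write_tiny_alignments(ref, recs)
}

test_that("streaming sanitization keeps mapped primaries and counts discards", {
  ref <- tiny_ref(len = 300L)
  bam <- ten_record_fixture(ref)
  out <- tempfile(fileext = ".bam")
  s <- stream_sanitize(bam, ref, out)
  expect_equal(s$records_in, 10L)
  expect_equal(s$records_out, 8L)
  expect_equal(sort(s$discarded_by_reason$reason), c("secondary", "unmapped"))
  expect_equal(s$discarded_by_reason$n, c(1L, 1L))
  expect_equal(s$records_in,
               s$records_out + sum(s$discarded_by_reason$n))
  expect_true(file.exists(paste0(out, ".bai")))
  g <- glance(s)
  expect_equal(g$discarded, 2L)
})

test_that("repeated runs produce byte-identical output", {
  ref <- tiny_ref(len = 300L)
  bam <- ten_record_fixture(ref)
  out <- tempfile(fileext = ".bam")
  stream_sanitize(bam, ref, out)
  first <- readBin(out, "raw", file.size(out))
  stream_sanitize(bam, ref, out)
  expect_identical(readBin(out, "raw", file.size(out)), first)
})

test_that("sanitizing its own output reproduces the record stream", {
  fx <- simulate_fixture(small_sim_params(seed = 21))
  out1 <- tempfile(fileext = ".bam"); out2 <- tempfile(fileext = ".bam")
  stream_sanitize(fx$bam, fx$ref, out1)
  s2 <- stream_sanitize(out1, fx$ref, out2)
  expect_equal(s2$records_in, s2$records_out)
  a <- read_alignments(out1); b <- read_alignments(out2)
  expect_identical(format_sam_records(a$records), format_sam_records(b$records))
  # headers differ only by the appended @PG line
  extra <- setdiff(b$header, a$header)
  expect_length(extra, 1L)
  expect_match(extra, "^@PG\t.*PP:bamscrub")
})

test_that("an empty (header-only) input yields a valid empty output", {
  ref <- tiny_ref(len = 300L)
  bam <- write_tiny_alignments(ref, list())
  out <- tempfile(fileext = ".bam")
  s <- stream_sanitize(bam, ref, out)
  expect_equal(s$records_out, 0L)
  expect_equal(nrow(read_alignments(out)$records), 0L)
  expect_equal(nrow(validate_bam_structure(out)), 0L)
})

test_that("header construction preserves @SQ and chains @PG", {
  h <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100", "@SQ\tSN:chr2\tLN:200")
  out <- build_output_header(h, "cmdline here")
  expect_identical(out[startsWith(out, "@SQ")], h[2:3])
  pg <- out[startsWith(out, "@PG")]
  expect_length(pg, 1L)
  expect_match(pg, "ID:bamscrub\t")
  expect_match(pg, "CL:cmdline here")
  expect_false(grepl("\tPP:", pg))
  # chaining onto an existing @PG
  out2 <- build_output_header(c(h, "@PG\tID:STAR\tPN:STAR"), "x")
  pg2 <- out2[startsWith(out2, "@PG")]
  expect_match(pg2[2], "\tPP:STAR")
  # no reference sequences at all
  expect_error(build_output_header("@HD\tVN:1.6", "x"), "no @SQ")
})

test_that("contigs in the BAM but not the reference are a hard failure", {
  ref <- tiny_ref(len = 300L)
  bam <- ten_record_fixture(ref)
  other <- tiny_ref(name = "chrOther", len = 300L)
  out <- tempfile(fileext = ".bam")
  expect_error(stream_sanitize(bam, other, out), "chrT")
})

test_that("output stays coordinate-sorted when single-end clip resolution
           shifts positions left", {
  ref <- tiny_ref(len = 300L)
  refseq <- function(s, e) ref_fetch(ref, "chrT", s, e)
  # r2 starts behind r1 but its leading clip moves it in front
  recs <- list(
    make_record(qname = "r1", pos = 100L, cigar = "10M",
                seq = refseq(100L, 110L)),
    make_record(qname = "r2", pos = 104L, cigar = "8S2M",
                seq = paste0(strrep("T", 8), refseq(104L, 106L)))
  )
  bam <- write_tiny_alignments(ref, recs)
  out <- tempfile(fileext = ".bam")
  s <- stream_sanitize(bam, ref, out)
  expect_equal(s$positions_shifted, 1L)
  r <- read_alignments(out)$records
  expect_equal(r$qname, c("r2", "r1"))
  expect_equal(r$pos, c(96L, 100L))
  expect_equal(nrow(validate_bam_structure(out)), 0L)
})
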