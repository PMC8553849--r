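blocks_of <- function(l) unname(as.matrix(l$blocks))

test_that("layout resolution reproduces the canonical rewrite cases", {
  # already reference-shaped
  l <- resolve_layout("100M", 1000L, paired = FALSE)
  expect_equal(l$new_pos, 1000L)
  expect_equal(blocks_of(l), matrix(c(1000L, 100L), 1))
  expect_equal(build_cigar(l), "100M")
  expect_equal(build_md(l), "100")

  # insertion: span grows by the insertion length at the 3' end
  l <- resolve_layout("50M2I48M", 1000L, paired = TRUE)
  expect_equal(blocks_of(l), matrix(c(1000L, 100L), 1))

  # deletion: reference span folded in, equal trim from the 3' end
  l <- resolve_layout("50M2D50M", 1000L, paired = FALSE)
  expect_equal(blocks_of(l), matrix(c(1000L, 100L), 1))

  # leading clip, single-end: start position moves left
  l <- resolve_layout("5S95M", 1000L, paired = FALSE)
  expect_equal(l$new_pos, 995L)
  expect_equal(blocks_of(l), matrix(c(995L, 100L), 1))

  # leading clip, paired: 5' stays, clip becomes a 3' extension
  l <- resolve_layout("5S95M", 1000L, paired = TRUE)
  expect_equal(l$new_pos, 1000L)
  expect_equal(blocks_of(l), matrix(c(1000L, 100L), 1))

  # spliced + insertion: junction coordinates preserved
  l <- resolve_layout("30M1I20M200N49M", 1000L, paired = FALSE)
  expect_equal(blocks_of(l), matrix(c(1000L, 1250L, 50L, 50L), 2))
  expect_equal(build_cigar(l), "50M200N50M")
  expect_equal(build_md(l), "100")
  expect_false(l$removed_splice)

  # deletion trim longer than the last exon removes the splice event
  l <- resolve_layout("50M5D43M100N2M", 1000L, paired = FALSE)
  expect_equal(blocks_of(l), matrix(c(1000L, 95L), 1))
  expect_true(l$removed_splice)
  expect_equal(build_cigar(l), "95M")
})

test_that("combined leading soft+hard clips act as one unit, and quality fill
           lands on the side where hard-clipped bases materialize", {
  l <- resolve_layout("3H5S92M", 1000L, paired = FALSE)
  expect_equal(l$new_pos, 992L)
  expect_equal(l$hard_clip_added, 3L)
  expect_equal(l$hard_fill_left, 3L)
  q <- rebuild_quals(strrep("I", 97), l)
  expect_equal(q, paste0("###", strrep("I", 97)))

  l <- resolve_layout("3H5S92M", 1000L, paired = TRUE)
  expect_equal(l$new_pos, 1000L)
  expect_equal(l$hard_fill_right, 3L)
  expect_equal(rebuild_quals(strrep("I", 97), l),
               paste0(strrep("I", 97), "###"))
  expect_equal(rebuild_quals("*", l), "*")
})

test_that("degenerate and before-contig layouts signal discard reasons", {
  expect_error(resolve_layout("5S3M", 2L, paired = FALSE),
               class = "bamscrub_layout_error")
  e <- tryCatch(resolve_layout("5S3M", 2L, paired = FALSE),
                bamscrub_layout_error = function(e) e)
  expect_equal(e$reason, "out_of_range")
  # trim with nothing left to trim from (no read-consuming ops at all)
  e <- tryCatch(resolve_layout("10D", 100L, paired = FALSE),
                bamscrub_layout_error = function(e) e)
  expect_equal(e$reason, "degenerate")
})

test_that("sequence rebuild concatenates reference blocks exactly", {
  ref <- tiny_ref(seq = "ACGTACGTACGTA", len = 13L)
  l <- list(blocks = tibble::tibble(ref_start = c(0L, 10L), length = c(3L, 2L)),
            total_query_len = 5L)
  expect_equal(rebuild_sequence(l, ref, "chrT"), "ACGGT")
  l2 <- list(blocks = tibble::tibble(ref_start = 0L, length = 13L))
  expect_equal(rebuild_sequence(l2, ref, "chrT"), "ACGTACGTACGTA")
  l3 <- list(blocks = tibble::tibble(ref_start = 10L, length = 5L))
  expect_error(rebuild_sequence(l3, ref, "chrT"), "out-of-bounds")
})

test_that("run-length layout agrees with the per-base oracle on random CIGARs", {
  set.seed(20260920)
  n_cases <- 10000
  failures <- character()
  for (i in seq_len(n_cases)) {
    cig <- rand_cigar()
    pos <- sample(0:400, 1)
    paired <- runif(1) < 0.5
    got <- layout_or_reason(resolve_layout(cig, pos, paired))
    want <- layout_or_reason(oracle_layout(cig, pos, paired))
    ok <- if (is.character(want) || is.character(got)) {
      identical(got, want)
    } else {
      identical(got$new_pos, want$new_pos) &&
        identical(got$blocks$ref_start, want$blocks$ref_start) &&
        identical(got$blocks$length, want$blocks$length) &&
        identical(got$removed_splice, want$removed_splice) &&
        identical(got$total_query_len, want$total_query_len)
    }
    if (!ok) {
      failures <- c(failures, sprintf("%s pos=%d paired=%s", cig, pos, paired))
    }
  }
  expect_identical(failures, character(0))
  expect_equal(n_cases, 10000)  # the suite really ran all cases
})

test_that("layout conserves read length (+hard clips) on random CIGARs", {
  set.seed(99)
  for (i in 1:500) {
    cig <- rand_cigar()
    ops <- parse_cigar(cig)
    l <- layout_or_reason(resolve_layout(cig, 500L, runif(1) < 0.5))
    if (is.character(l)) next
    expect_equal(l$total_query_len,
                 cigar_query_length(ops) + sum(ops$len[ops$op == "H"]))
    expect_true(all(diff(l$blocks$ref_start) >
                      l$blocks$length[-nrow(l$blocks)] - 1L))
  }
})
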