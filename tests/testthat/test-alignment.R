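test_that("global alignment handles identity, simple gaps and degenerate inputs", {
  p <- alignment_params()
  aln <- global_align("ACGT", "ACGT", p)
  expect_identical(aln$gapped_a, "ACGT")
  expect_identical(aln$gapped_b, "ACGT")
  expect_equal(aln$score, 8)

  aln2 <- global_align("ACGT", "AGT", p)
  expect_equal(aln2$score, enumerate_best_score("ACGT", "AGT"))
  expect_equal(sum(strsplit(aln2$gapped_b, "")[[1]] == "-"), 1L)
  expect_identical(gsub("-", "", aln2$gapped_a), "ACGT")
  expect_identical(gsub("-", "", aln2$gapped_b), "AGT")

  aln3 <- global_align("", "AA", p)
  expect_identical(aln3$gapped_a, "--")
  expect_identical(aln3$gapped_b, "AA")
  expect_equal(aln3$score, -10 + 2 * -1)

  expect_equal(global_align("", "", p)$n_columns, 0L)
  expect_error(global_align("ACGU", "ACG", p), "non-DNA")
})

test_that("alignment never produces a column gapped in both rows and strips to its inputs", {
  set.seed(401)
  p <- alignment_params()
  for (i in 1:25) {
    a <- paste0(sample(c("A", "C", "G", "T"), sample(0:40, 1), TRUE),
                collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T"), sample(0:40, 1), TRUE),
                collapse = "")
    aln <- global_align(a, b, p)
    ga <- strsplit(aln$gapped_a, "")[[1]]
    gb <- strsplit(aln$gapped_b, "")[[1]]
    expect_equal(length(ga), length(gb))
    expect_false(any(ga == "-" & gb == "-"))
    expect_identical(gsub("-", "", aln$gapped_a), a)
    expect_identical(gsub("-", "", aln$gapped_b), b)
    expect_equal(score_gapped(aln$gapped_a, aln$gapped_b), aln$score)
  }
})

test_that("alignment score matches exhaustive enumeration on short sequences", {
  seqs <- all_seqs(0:3)
  p <- alignment_params()
  for (a in seqs) for (b in seqs) {
    expect_equal(global_align(a, b, p)$score, enumerate_best_score(a, b),
                 info = paste(a, "/", b))
  }
})

test_that("alignment score is symmetric under argument swap", {
  set.seed(402)
  p <- alignment_params()
  for (i in 1:10) {
    a <- paste0(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T"), 17, TRUE), collapse = "")
    expect_equal(global_align(a, b, p)$score, global_align(b, a, p)$score)
  }
})

test_that("gap-excluded identity counts only ungapped columns", {
  p <- alignment_params()
  expect_equal(alignment_identity(global_align("ACGT", "ACGT", p)), 1.0)
  expect_equal(alignment_identity(global_align("ACGT", "ACGA", p)), 0.75)
  # hand-built alignment: 3 ungapped columns, 3 matches
  aln <- structure(list(gapped_a = "AC-T", gapped_b = "ACGT", score = 0,
                        n_columns = 4L, params = p),
                   class = "pairwise_alignment")
  expect_equal(alignment_identity(aln), 1.0)
  expect_equal(alignment_identity(global_align("", "AA", p)), 0)
})

test_that("flank identity counts the first W ungapped columns per side", {
  p <- alignment_params()
  set.seed(403)
  s <- paste0(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  fi <- flank_identity(global_align(s, s, p), 100, W = 45)
  expect_equal(fi$left_identity, 1.0)
  expect_equal(fi$right_identity, 1.0)
  expect_equal(fi$combined_identity, 1.0)
  expect_equal(fi$counted_left, 45L)
  expect_equal(fi$counted_right, 45L)

  # truncation at the sequence end
  fi2 <- flank_identity(global_align(s, s, p), 10, W = 45)
  expect_equal(fi2$counted_left, 10L)
  expect_equal(fi2$counted_right, 45L)

  expect_error(flank_identity(global_align(s, s, p), 500), "anchor")
})

test_that("flank identity equals the hand count with planted mismatches", {
  set.seed(404)
  a <- paste0(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  b <- a
  # plant exactly 5 mismatches among the 45 columns left of anchor 60
  flip <- function(ch) c(A = "C", C = "G", G = "T", T = "A")[[ch]]
  for (pos in c(20, 25, 33, 47, 59))
    substr(b, pos, pos) <- flip(substr(a, pos, pos))
  fi <- flank_identity(global_align(a, b, alignment_params()), 60, W = 45)
  expect_equal(fi$left_identity, 40 / 45)
  expect_equal(fi$right_identity, 1.0)
  expect_equal(fi$combined_identity, (40 + 45) / 90)
})

test_that("flank identity skips gap columns and an extra mismatch never raises a side", {
  p <- alignment_params()
  set.seed(405)
  for (i in 1:10) {
    a <- paste0(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    b <- paste0(substr(a, 1, 60), substr(a, 81, 150))  # 20-bp deletion
    aln <- global_align(a, b, p)
    ch <- list(a = strsplit(aln$gapped_a, "")[[1]],
               b = strsplit(aln$gapped_b, "")[[1]])
    anchor <- 70L
    fi <- flank_identity(aln, anchor, W = 45)
    expect_lte(fi$counted_left + fi$counted_right, 90L)
    # counted columns are by construction ungapped: identities reachable
    # only if every counted column has two bases
    expect_true(fi$left_identity >= 0 && fi$left_identity <= 1)

    # degrade one counted position on the left and recompute
    b2 <- b
    substr(b2, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(b, 10, 10))[1]
    fi2 <- flank_identity(global_align(a, b2, p), anchor, W = 45)
    expect_lte(fi2$left_identity, fi$left_identity)
  }
})

test_that("alignment params validate their invariants", {
  expect_error(alignment_params(match = -3, mismatch = 2), "match")
  expect_error(alignment_params(gap_open = -1, gap_extend = -5), "gap_open")
  expect_error(alignment_params(gap_extend = 1), "gap_open")
})
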