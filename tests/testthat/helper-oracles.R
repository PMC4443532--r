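# Independent oracles used across the suite.

# Score a pair of gapped rows under the affine model:
# each gap run costs gap_open + L * gap_extend.
score_gapped <- function(ga, gb, match = 2, mismatch = -3,
                         gap_open = -10, gap_extend = -1) {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  stopifnot(length(a) == length(b), !any(a == "-" & b == "-"))
  s <- 0
  run_a <- FALSE; run_b <- FALSE
  for (i in seq_along(a)) {
    if (a[i] == "-") {
      s <- s + gap_extend + if (!run_a) gap_open else 0
      run_a <- TRUE; run_b <- FALSE
    } else if (b[i] == "-") {
      s <- s + gap_extend + if (!run_b) gap_open else 0
      run_b <- TRUE; run_a <- FALSE
    } else {
      s <- s + if (a[i] == b[i] && a[i] != "N") match else mismatch
      run_a <- FALSE; run_b <- FALSE
    }
  }
  s
}

# Exhaustive enumeration of every global alignment (as move sequences),
# scoring each complete alignment with score_gapped.  Feasible only for
# very short sequences.
enumerate_best_score <- function(a, b, ...) {
  best <- -Inf
  recurse <- function(i, j, ga, gb) {
    if (i == nchar(a) && j == nchar(b)) {
      best <<- max(best, score_gapped(ga, gb, ...))
      return(invisible())
    }
    if (i < nchar(a) && j < nchar(b))
      recurse(i + 1, j + 1, paste0(ga, substr(a, i + 1, i + 1)),
              paste0(gb, substr(b, j + 1, j + 1)))
    if (i < nchar(a))
      recurse(i + 1, j, paste0(ga, substr(a, i + 1, i + 1)), paste0(gb, "-"))
    if (j < nchar(b))
      recurse(i, j + 1, paste0(ga, "-"), paste0(gb, substr(b, j + 1, j + 1)))
  }
  recurse(0, 0, "", "")
  best
}

# Independent score-only affine DP written directly over a 3-state array
# (no traceback, different code path from the package implementation).
oracle_affine_score <- function(a, b, match = 2, mismatch = -3,
                                gap_open = -10, gap_extend = -1) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) X[2:(n + 1), 1] <- gap_open + (1:n) * gap_extend
  if (m >= 1) Y[1, 2:(m + 1)] <- gap_open + (1:m) * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend,
                             Y[i, j + 1] + gap_open + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             X[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
    }
  }
  if (n == 0 && m == 0) 0 else max(M[n + 1, m + 1], X[n + 1, m + 1],
                                   Y[n + 1, m + 1])
}

# All sequences over an alphabet with lengths in `lens`.
all_seqs <- function(lens, alphabet = c("A", "C")) {
  out <- character(0)
  for (L in lens) {
    if (L == 0) { out <- c(out, ""); next }
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(grid, 1, paste0, collapse = ""))
  }
  out
}

# Maximum-cardinality one-to-one matching of two sorted column vectors
# within tol, by exhaustive enumeration (small inputs only).
oracle_max_matching <- function(colsA, colsB, tol) {
  best <- 0L
  nA <- length(colsA); nB <- length(colsB)
  recurse <- function(i, usedB, count) {
    if (i > nA) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, usedB, count)                  # leave A_i unmatched
    for (j in seq_len(nB)) {
      if (!usedB[j] && abs(colsA[i] - colsB[j]) <= tol) {
        usedB[j] <- TRUE
        recurse(i + 1L, usedB, count + 1L)
        usedB[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nB), 0L)
  best
}

# Small hand-rolled FASTA/GFF fixture written to a temp dir.
write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Toy two-exon gene on a synthetic chromosome (plus strand).
toy_genome <- function() {
  stats::setNames(paste0(
    strrep("ACGT", 5),                 # 20 bp pad
    "ATGGCCGCA",                       # exon 1 start of CDS (9 bp)
    "GTAAGCATTTTCCCCTAG",              # intron 1 (18 bp, GT..AG)
    "GGCTCATAA",                       # exon 2 end of CDS (9 bp)
    strrep("TTGC", 5)), "chr1")        # 20 bp pad
}

toy_model <- function() {
  intronloss:::new_gene_model(
    "g1", "g1.t1", "chr1", "+",
    exons = rbind(c(20L, 29L), c(47L, 56L)),
    cds = rbind(c(20L, 29L), c(47L, 56L)))
}
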