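test_that("intron projection maps spliced offsets through gap columns", {
  genome <- toy_genome()
  m <- toy_model()          # two 9-bp exons, one intron after offset 9
  spliced <- spliced_sequence(m, genome)
  p <- alignment_params()

  # ungapped alignment: boundary at column 9
  aln <- global_align(spliced, spliced, p)
  pl <- project_introns(m, genome, aln, "a")
  expect_equal(pl$column, 9L)
  expect_equal(pl$intron_index, 1L)

  # recipient with a 3-bp deletion upstream: donor row gains no gaps, but
  # projecting the RECIPIENT's intron must skip its 3 gap columns
  recip <- paste0(substr(spliced, 4, 9), substr(spliced, 10, 18))
  aln2 <- global_align(spliced, recip, p)
  mr <- intronloss:::new_gene_model("g2", "g2.t", "chr1", "+",
                                    rbind(c(23L, 29L), c(47L, 56L)),
                                    rbind(c(23L, 29L), c(47L, 56L)))
  # row b strips to recip only if the deletion matches annotation
  expect_identical(gsub("-", "", aln2$gapped_b),
                   spliced_sequence(mr, genome))
  plb <- project_introns(mr, genome, aln2, "b")
  nga <- sum(strsplit(aln2$gapped_b, "")[[1]][1:9] == "-")
  expect_equal(plb$column, 6L + nga)

  single <- intronloss:::new_gene_model("g3", "g3.t", "chr1", "+",
                                        rbind(c(20L, 29L)), NULL)
  aln3 <- global_align(spliced_sequence(single, genome),
                       spliced, p)
  expect_equal(nrow(project_introns(single, genome, aln3, "a")), 0L)
})

test_that("projection refuses a row that does not strip to the gene's sequence", {
  genome <- toy_genome()
  m <- toy_model()
  aln <- global_align("ACGTACGT", "ACGTACGT", alignment_params())
  expect_error(project_introns(m, genome, aln, "a"), "does not strip")
})

test_that("diff_structures matches identical placements and reports extras", {
  pl <- function(idx, col, phase = 0L, context = "CDS", len = 100L)
    data.frame(intron_index = idx, column = col, phase = phase,
               context = context, length = len, start = 0L, end = len)
  a <- pl(1:3, c(10L, 50L, 90L))
  d <- diff_structures(a, a, tol = 0L)
  expect_equal(nrow(d$matched), 3L)
  expect_equal(nrow(d$only_in_a), 0L)
  expect_equal(nrow(d$only_in_b), 0L)

  b <- pl(1:4, c(10L, 50L, 55L, 90L))
  d2 <- diff_structures(a, b, tol = 0L)
  expect_equal(d2$only_in_b$intron_index, 3L)
  expect_equal(d2$only_in_b$column, 55L)
})

test_that("nearest placement wins with ties broken toward the smaller column", {
  pl <- function(idx, col) data.frame(intron_index = idx, column = col,
                                      phase = 0L, context = "CDS",
                                      length = 100L, start = 0L, end = 100L)
  a <- pl(1L, 50L)
  b <- pl(1:2, c(48L, 52L))       # equidistant within tol 2
  d <- diff_structures(a, b, tol = 2L)
  expect_equal(d$matched$index_b, 1L)   # smaller column wins the tie
  b2 <- pl(1:2, c(47L, 51L))
  d2 <- diff_structures(a, b2, tol = 4L)
  expect_equal(d2$matched$index_b, 2L)  # distance 1 beats distance 3
})

test_that("greedy matching reaches the exhaustive maximum cardinality", {
  set.seed(406)
  for (i in 1:40) {
    nA <- sample(0:4, 1); nB <- sample(0:4, 1)
    colsA <- sort(sample(0:30, nA))
    colsB <- sort(sample(0:30, nB))
    tol <- sample(0:4, 1)
    pa <- data.frame(intron_index = seq_len(nA), column = colsA,
                     phase = rep(0L, nA), context = rep("CDS", nA),
                     length = rep(50L, nA), start = rep(0L, nA),
                     end = rep(50L, nA))
    pb <- data.frame(intron_index = seq_len(nB), column = colsB,
                     phase = rep(0L, nB), context = rep("CDS", nB),
                     length = rep(50L, nB), start = rep(0L, nB),
                     end = rep(50L, nB))
    d <- diff_structures(pa, pb, tol)
    expect_equal(nrow(d$matched), oracle_max_matching(colsA, colsB, tol))
    expect_equal(nrow(d$matched) + nrow(d$only_in_a), nA)
    expect_equal(nrow(d$matched) + nrow(d$only_in_b), nB)
  }
})

test_that("genomic retention calls exact substrings, rejects noise, guards short queries", {
  set.seed(407)
  locus <- paste0(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  query <- substr(locus, 201, 320)
  expect_identical(check_genomic_retention(query, locus), "retained")

  foreign <- paste0(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  # sliding-window oracle: best ungapped-window identity far below 0.70
  best <- 0
  qv <- strsplit(foreign, "")[[1]]
  lv <- strsplit(locus, "")[[1]]
  for (s in 0:(600 - 120)) {
    best <- max(best, mean(qv == lv[(s + 1):(s + 120)]))
  }
  expect_lt(best, 0.55)
  expect_identical(check_genomic_retention(foreign, locus), "absent")

  expect_identical(check_genomic_retention("ACGTACGT", locus), "unknown")
})

test_that("retention tolerates divergence within its identity floor", {
  set.seed(408)
  locus <- paste0(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  q <- strsplit(substr(locus, 101, 250), "")[[1]]
  hit <- which(runif(length(q)) < 0.15)
  for (p in hit) q[p] <- sample(setdiff(c("A", "C", "G", "T"), q[p]), 1)
  expect_identical(check_genomic_retention(paste0(q, collapse = ""), locus),
                   "retained")
})

test_that("classification is invariant under strand flips of either gene", {
  for (strands in list(c("+", "+"), c("-", "+"), c("+", "-"), c("-", "-"))) {
    b <- generate_locus_pair(generator_config(
      planted = list(planted_event("IIL", intron_index = 2,
                                   up_del_bp = 7, down_del_bp = 5)),
      divergence = 0.03, seed = 77, strand = strands, n_exons = c(5L, 5L)))
    ev <- detect_bundle(b)
    expect_equal(nrow(ev), 1L, info = paste(strands, collapse = ""))
    expect_identical(ev$type, "IIL")
    expect_equal(ev$up_indel_bp, 7L)
    expect_equal(ev$down_indel_bp, 5L)
  }
})

test_that("a PIL event never carries exonic indels; an IIL always does", {
  b <- generate_cohort(60, seed = 88)
  ev <- detect_bundle(b)
  pil <- ev[ev$type == "PIL", ]
  expect_true(all(pil$up_indel_bp == 0 & pil$down_indel_bp == 0 &
                  pil$whole_exon_lost_bp == 0))
  expect_true(all(pil$retention == "absent"))
  iil <- ev[ev$type == "IIL", ]
  expect_true(all(iil$up_indel_bp + iil$down_indel_bp +
                  iil$whole_exon_lost_bp >= 1))
  expect_true(all(iil$retention == "absent"))
  expect_true(all(ev$retention[ev$type == "DE_EXONIZATION"] == "retained"))
  expect_true(all(ev$retention[ev$type == "EXON_DELETION"] == "absent"))
})

test_that("every unmatched donor intron yields exactly one record", {
  b <- generate_cohort(36, seed = 89)
  ev <- detect_bundle(b)
  # each planted event consumes its donor introns exactly once: counts match
  expect_equal(nrow(ev), nrow(b$truth))
  expect_setequal(ev$event_id, b$truth$event_id)
})

test_that("frame-disrupting indels are flagged but kept", {
  b <- generate_locus_pair(generator_config(
    planted = list(planted_event("IIL", intron_index = 2,
                                 up_del_bp = 22, down_del_bp = 9)),
    divergence = 0, seed = 90, n_exons = c(5L, 5L)))
  ev <- detect_bundle(b)
  expect_true(ev$frame_disrupting)       # 31 bp net, not 0 mod 3
  b2 <- generate_locus_pair(generator_config(
    planted = list(planted_event("IIL", intron_index = 2,
                                 up_del_bp = 21, down_del_bp = 9)),
    divergence = 0, seed = 90, n_exons = c(5L, 5L)))
  expect_false(detect_bundle(b2)$frame_disrupting)
})

test_that("polarization follows outgroup intron presence", {
  b <- generate_locus_pair(generator_config(
    planted = list(planted_event("PIL", intron_index = 2)),
    divergence = 0, seed = 91))
  ev <- detect_bundle(b)
  expect_identical(ev$direction, "unpolarized")
  # outgroup carrying the intron at the homologous offset
  off <- ev$donor_offset
  expect_identical(polarize(ev, outgroup_offsets = off)$direction,
                   "polarized_loss")
  # outgroup lacking the intron: parsimony cannot orient the change
  expect_identical(polarize(ev, outgroup_offsets = off + 500L)$direction,
                   "unpolarized")
  expect_identical(polarize(ev, NULL)$direction, "unpolarized")
})

test_that("outgroup offsets project through a third genome", {
  # outgroup = an undiverged copy of the donor: offsets equal donor offsets
  b <- generate_locus_pair(generator_config(
    planted = list(planted_event("PIL", intron_index = 2)),
    divergence = 0, seed = 92))
  donor <- b$models_a[[1]]
  off <- project_outgroup_offsets(donor, donor, b$genome_a, b$genome_a)
  expect_equal(off, intronloss:::intron_offsets(donor, "transcript"),
               ignore_attr = TRUE)
  ev <- detect_bundle(b)
  expect_identical(polarize(ev, off)$direction, "polarized_loss")
})
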