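test_that("identical configs produce byte-identical bundles", {
  cfg <- generator_config(seed = 501, divergence = 0.05,
                          planted = list(planted_event("PIL", intron_index = 2)))
  d1 <- tempfile(); d2 <- tempfile()
  generate_locus_pair(cfg, dir = d1)
  generate_locus_pair(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("generated annotations re-parse cleanly with GT/AG introns and intact ORFs", {
  b <- generate_locus_pair(generator_config(
    seed = 502, divergence = 0.08, frame_preserving = TRUE,
    planted = list(planted_event("IIL", intron_index = 2,
                                 up_del_bp = 12, down_del_bp = 9))))
  d <- tempfile()
  write_bundle(b, d)
  for (side in c("a", "b")) {
    g <- load_genome(file.path(d, paste0("genome_", side, ".fa")))
    mods <- load_gene_models(file.path(d, paste0("genes_", side, ".gff3")))
    expect_equal(length(mods), 1L)
    m <- mods[[1]]
    ii <- introns_of(m, g)
    expect_true(all(ii$donor2 == "GT"))
    expect_true(all(ii$acceptor2 == "AG"))
    cds <- spliced_sequence(m, g, "cds")
    expect_identical(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("ORFs stay intact under frame-preserving divergence for every event type", {
  specs <- list(
    planted_event("PIL", intron_index = 2),
    planted_event("IIL", intron_index = 2, up_del_bp = 6, down_del_bp = 3),
    planted_event("IIL", intron_index = 2, whole_exon_codel = TRUE),
    planted_event("DE_INTRONIZATION", intron_index = 2),
    planted_event("DE_EXONIZATION", exon_index = 3),
    planted_event("EXON_DELETION", exon_index = 3))
  for (i in seq_along(specs)) {
    b <- generate_locus_pair(generator_config(
      seed = 510 + i, divergence = 0.08, frame_preserving = TRUE,
      n_exons = c(5L, 5L), planted = specs[i]))
    m <- b$models_b[[1]]
    cds <- spliced_sequence(m, b$genome_b, "cds")
    expect_equal(nchar(cds) %% 3, 0, info = specs[[i]]$type)
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                        seq(3, nchar(cds), 3))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")),
                 info = specs[[i]]$type)
  }
})

test_that("a planted precise loss conserves sequence outside the intron", {
  cfg <- generator_config(seed = 503, divergence = 0,
                          planted = list(planted_event("PIL", intron_index = 1)))
  b <- generate_locus_pair(cfg)
  la <- nchar(b$genome_a[[1]]); lb <- nchar(b$genome_b[[1]])
  lost <- b$truth$lost_intron_length
  expect_equal(lb, la - lost)
  # spliced transcripts are identical at zero divergence
  expect_identical(spliced_sequence(b$models_a[[1]], b$genome_a),
                   spliced_sequence(b$models_b[[1]], b$genome_b))
})

test_that("generator refuses invalid planted events", {
  expect_error(generate_locus_pair(generator_config(
    seed = 504, n_exons = c(4L, 4L),
    planted = list(planted_event("PIL", intron_index = 9)))),
    "nonexistent intron")
  expect_error(generate_locus_pair(generator_config(
    seed = 505, n_exons = c(4L, 4L),
    planted = list(planted_event("EXON_DELETION", exon_index = 4)))),
    "internal exon")
  expect_error(planted_event("IIL", intron_index = 1),
               "up_del_bp")
  expect_error(generator_config(seed = 1, divergence = 0.7), "divergence")
  expect_error(generator_config(), "seed")
})

test_that("simulated support is Poisson with the requested means and is seeded", {
  truth <- data.frame(event_id = sprintf("e%04d", 1:1000),
                      stringsAsFactors = FALSE)
  s1 <- simulate_support(truth, mean_rna = 20, mean_wgs = 9, seed = 506)
  s2 <- simulate_support(truth, mean_rna = 20, mean_wgs = 9, seed = 506)
  expect_identical(s1, s2)
  rna <- s1$read_count[s1$source == "rna_junction"]
  # sample mean within 3 standard errors of the Poisson mean
  expect_lt(abs(mean(rna) - 20), 3 * sqrt(20 / 1000))
  s0 <- simulate_support(truth, mean_rna = 0, mean_wgs = 0, seed = 507)
  expect_true(all(s0$read_count == 0))
})

test_that("simulated genotypes respect carrier and missing rates", {
  truth <- data.frame(event_id = "e1", stringsAsFactors = FALSE)
  g <- simulate_population(truth, n_lines = 10000, carrier_freq = 0.5,
                           missing_rate = 0, seed = 508)
  freq <- mean(g$state == "carrier")
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 10000))

  gfix <- simulate_population(truth, n_lines = 180, carrier_freq = 1,
                              missing_rate = 0, seed = 509)
  expect_identical(fixation_survey(gfix$state)$status, "fixed")

  gmiss <- simulate_population(truth, n_lines = 180, carrier_freq = 1,
                               missing_rate = 1, seed = 510)
  expect_identical(fixation_survey(gmiss$state)$status, "no_data")
})

test_that("exon-level events are never planted on terminal exons by the cohort generator", {
  b <- generate_cohort(30, seed = 511)
  for (i in seq_len(nrow(b$truth))) {
    tr <- b$truth[i, ]
    if (tr$type %in% c("DE_EXONIZATION", "EXON_DELETION") ||
        tr$whole_exon_lost_bp > 0) {
      donor <- b$models_a[[tr$donor_gene]]
      expect_gt(tr$exon_index, 1L)
      expect_lt(tr$exon_index, nrow(donor$exons))
    }
  }
})
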