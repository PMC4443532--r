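test_that("load_genome reads multi-record FASTA, uppercases and validates", {
  f <- write_lines_tmp(c(">c1", "ac", "gt", ">c2", "NNN"), ".fa")
  g <- load_genome(f)
  expect_identical(g[["c1"]], "ACGT")
  expect_identical(g[["c2"]], "NNN")

  f1 <- write_lines_tmp(c(">c1", "ACGT"), ".fa")
  expect_identical(unname(load_genome(f1)["c1"]), "ACGT")

  fdup <- write_lines_tmp(c(">c1", "AC", ">c1", "GT"), ".fa")
  expect_error(load_genome(fdup), "duplicate.*c1")

  fempty <- write_lines_tmp(character(0), ".fa")
  expect_error(load_genome(fempty))
})

test_that("GFF3 coordinates convert to 0-based half-open and minus-strand exons reverse", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t30\t.\t+\t.\tID=gp",
    "c1\tsrc\tmRNA\t1\t30\t.\t+\t.\tID=tp;Parent=gp",
    "c1\tsrc\texon\t1\t4\t.\t+\t.\tID=tp.e1;Parent=tp",
    "c1\tsrc\texon\t21\t30\t.\t+\t.\tID=tp.e2;Parent=tp",
    "c1\tsrc\tgene\t1\t30\t.\t-\t.\tID=gm",
    "c1\tsrc\tmRNA\t1\t30\t.\t-\t.\tID=tm;Parent=gm",
    "c1\tsrc\texon\t1\t10\t.\t-\t.\tID=tm.e1;Parent=tm",
    "c1\tsrc\texon\t21\t30\t.\t-\t.\tID=tm.e2;Parent=tm"), ".gff3")
  models <- load_gene_models(gff)
  expect_equal(unname(models[["tp"]]$exons[1, ]), c(0L, 4L))
  # minus strand: the 21..30 interval ([20,30)) comes first in coding order
  expect_equal(unname(models[["tm"]]$exons[1, ]), c(20L, 30L))
  expect_equal(unname(models[["tm"]]$exons[2, ]), c(0L, 10L))
})

test_that("GFF3 structural errors are caught", {
  no_exon <- write_lines_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t30\t.\t+\t.\tID=g",
    "c1\tsrc\tmRNA\t1\t30\t.\t+\t.\tID=t;Parent=g"), ".gff3")
  expect_error(load_gene_models(no_exon), "no exon children")

  outside <- write_lines_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t10\t30\t.\t+\t.\tID=g",
    "c1\tsrc\tmRNA\t10\t30\t.\t+\t.\tID=t;Parent=g",
    "c1\tsrc\texon\t1\t30\t.\t+\t.\tID=t.e1;Parent=t"), ".gff3")
  expect_error(load_gene_models(outside), "outside parent gene span")

  cds_out <- write_lines_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t30\t.\t+\t.\tID=g",
    "c1\tsrc\tmRNA\t1\t30\t.\t+\t.\tID=t;Parent=g",
    "c1\tsrc\texon\t1\t10\t.\t+\t.\tID=t.e1;Parent=t",
    "c1\tsrc\tCDS\t15\t25\t.\t+\t.\tID=t.c1;Parent=t"), ".gff3")
  expect_error(load_gene_models(cds_out), "CDS interval not contained")
})

test_that("spliced_sequence concatenates exons and reverse-complements on minus", {
  genome <- c(chr = "AAATTTTGGG")
  plus <- intronloss:::new_gene_model("g", "g.t", "chr", "+",
                                      rbind(c(0L, 3L), c(7L, 10L)), NULL)
  expect_identical(spliced_sequence(plus, genome), "AAAGGG")
  minus <- intronloss:::new_gene_model("g", "g.t", "chr", "-",
                                       rbind(c(7L, 10L), c(0L, 3L)), NULL)
  expect_identical(spliced_sequence(minus, genome), "CCCTTT")
  expect_error(spliced_sequence(plus, genome, "cds"), "no cds")
})

test_that("introns_of reports interval, length, phase and splice dinucleotides", {
  genome <- toy_genome()
  m <- toy_model()
  ii <- introns_of(m, genome)
  expect_equal(nrow(ii), 1L)
  expect_equal(ii$start, 29L)
  expect_equal(ii$end, 47L)
  expect_equal(ii$length, 18L)
  expect_equal(ii$phase, 9L %% 3L)
  expect_identical(ii$donor2, "GT")
  expect_identical(ii$acceptor2, "AG")
  expect_identical(ii$context, "CDS")

  single <- intronloss:::new_gene_model("g", "g.t", "chr1", "+",
                                        rbind(c(20L, 29L)), NULL)
  expect_equal(nrow(introns_of(single, genome)), 0L)
})

test_that("an intron 3' of the stop codon is UTR3 with NA phase", {
  # exon2 split: CDS ends inside exon2, then an annotated-UTR intron
  genome <- c(chr1 = paste0(strrep("A", 10),
                            "ATGCCC",          # exon1: CDS start
                            "GTTTAG",          # intron 1 (CDS)
                            "GGGTAA", "CCTT",  # exon2: CDS end + 3'UTR bit
                            "GTCCAG",          # intron 2 entirely in 3'UTR
                            "ACGT",            # exon3: pure 3'UTR
                            strrep("A", 10)))
  m <- intronloss:::new_gene_model(
    "g", "g.t", "chr1", "+",
    exons = rbind(c(10L, 16L), c(22L, 32L), c(38L, 42L)),
    cds = rbind(c(10L, 16L), c(22L, 28L)), utr_annotated = TRUE)
  ii <- introns_of(m, genome)
  expect_equal(ii$context, c("CDS", "UTR3"))
  expect_equal(ii$phase, c(0L, NA_integer_))
})

test_that("gene models round-trip through GFF3 writing and parsing", {
  b <- generate_locus_pair(generator_config(
    seed = 301, divergence = 0.05, strand = c("+", "-"),
    utr5_len = 30, utr3_len = 45,
    planted = list(planted_event("PIL", intron_index = 2))))
  for (side in c("a", "b")) {
    mods <- b[[paste0("models_", side)]]
    f <- tempfile(fileext = ".gff3")
    write_gene_models(mods, f)
    re <- load_gene_models(f)
    m0 <- mods[[1]]; m1 <- re[[m0$transcript_id]]
    expect_equal(m1$exons, m0$exons, ignore_attr = TRUE)
    expect_equal(m1$cds, m0$cds, ignore_attr = TRUE)
    expect_identical(m1$strand, m0$strand)
    expect_identical(m1$utr_annotated, m0$utr_annotated)
  }
})

test_that("intron count equals exon count minus one, and CDS is a substring of the transcript", {
  for (seed in c(11, 12, 13)) {
    b <- generate_locus_pair(generator_config(seed = seed, utr5_len = 25,
                                              utr3_len = 40))
    m <- b$models_a[[1]]
    expect_equal(nrow(introns_of(m, b$genome_a)), nrow(m$exons) - 1L)
    tx <- spliced_sequence(m, b$genome_a, "transcript")
    cds <- spliced_sequence(m, b$genome_a, "cds")
    expect_true(grepl(cds, tx, fixed = TRUE))
  }
})

test_that("primary_transcripts keeps the longest CDS, ties broken lexicographically", {
  mk <- function(tid, cds_end) intronloss:::new_gene_model(
    "g1", tid, "chr", "+", rbind(c(0L, 30L)), rbind(c(0L, cds_end)))
  models <- list(a = mk("t.b", 30L), b = mk("t.a", 30L), c = mk("t.c", 15L))
  kept <- primary_transcripts(models)
  expect_equal(length(kept), 1L)
  expect_identical(kept[[1]]$transcript_id, "t.a")
})
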