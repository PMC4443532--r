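Package: intronloss
Title: Detection and Classification of Intron Loss Events Between Orthologous Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the exon-intron structures of orthologous genes between
    closely related genomes and classifies every structural difference into one
    of five event types: precise intron loss, imprecise intron loss (including
    whole-exon co-deletion), de-intronization, de-exonization, and exon
    deletion. Provides a deterministic global affine-gap aligner for spliced
    transcripts, gap-excluded flank-identity windows, read-support filtering of
    candidate events, a population fixation survey, and a contingency-table
    analysis of the detection bias against imprecise losses when alignments to
    a diverged reference genome are filtered by identity. A synthetic-data
    module generates two-species ortholog fixtures with planted ground-truth
    events so the entire pipeline can be exercised without external genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
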