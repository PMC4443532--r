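#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline in one object.
#'
#' @param params [alignment_params()] for the spliced-transcript alignment.
#' @param W Flank window width in ungapped bp per side (default 45).
#' @param tol Intron position matching tolerance in columns (default 0).
#' @param adjacency_window Columns per side linking an exonic gap run to an
#'   intron site (default 15).
#' @param thresholds [support_thresholds()] for read evidence.
#' @param retention_identity,retention_coverage Retention-check floors.
#' @param q Quantile for the alignment-identity filter (default 0.25).
#' @param seed Seed recorded with the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(params = alignment_params(), W = 45L, tol = 0L,
                            adjacency_window = 15L,
                            thresholds = support_thresholds(),
                            retention_identity = 0.70,
                            retention_coverage = 0.70,
                            q = 0.25, seed = 1L) {
  structure(list(params = params, W = as.integer(W), tol = as.integer(tol),
                 adjacency_window = as.integer(adjacency_window),
                 thresholds = thresholds,
                 retention_identity = retention_identity,
                 retention_coverage = retention_coverage,
                 q = q, seed = as.integer(seed)),
            class = "pipeline_config")
}

as_classify_config <- function(cfg) {
  classify_config(tol = cfg$tol, adjacency_window = cfg$adjacency_window,
                  retention_identity = cfg$retention_identity,
                  retention_coverage = cfg$retention_coverage)
}

#' Detect events for one ortholog pair
#'
#' Aligns the two spliced sequences (transcript level when both models have
#' annotated UTRs, CDS level otherwise), projects and matches intron
#' positions, and classifies every structural difference.
#'
#' @param donor,recipient `gene_model`s (the first ortholog-table column is
#'   the donor candidate).
#' @param genome_donor,genome_recipient Genome vectors.
#' @param cfg A [pipeline_config()].
#' @return `loss_events` data.frame.
#' @export
detect_pair <- function(donor, recipient, genome_donor, genome_recipient,
                        cfg = pipeline_config()) {
  region <- if (donor$utr_annotated && recipient$utr_annotated)
    "transcript" else "cds"
  if (nrow(donor$cds) == 0L || nrow(recipient$cds) == 0L)
    region <- "transcript"
  aln <- global_align(spliced_sequence(donor, genome_donor, region),
                      spliced_sequence(recipient, genome_recipient, region),
                      cfg$params)
  pA <- project_introns(donor, genome_donor, aln, "a", region)
  pB <- project_introns(recipient, genome_recipient, aln, "b", region)
  diff <- diff_structures(pA, pB, cfg$tol)
  classify_events(diff, aln, donor, recipient, genome_donor,
                  genome_recipient, as_classify_config(cfg), region)
}

#' Run the detection pipeline over a fixture bundle
#'
#' @param bundle A `fixture_bundle` (in memory).
#' @param cfg A [pipeline_config()].
#' @return `loss_events` data.frame over all ortholog pairs.
#' @export
detect_bundle <- function(bundle, cfg = pipeline_config()) {
  detect_all(bundle$models_a, bundle$models_b, bundle$genome_a,
             bundle$genome_b, bundle$orthologs, cfg)
}

#' Detect events for every pair of an ortholog table
#'
#' @param models_a,models_b Lists of `gene_model`s (named by transcript id).
#' @param genome_a,genome_b Genome vectors.
#' @param orthologs data.frame with columns gene_a, gene_b.
#' @param cfg A [pipeline_config()].
#' @param verbose Log skipped pairs with reason codes to stderr.
#' @return `loss_events` data.frame.
#' @export
detect_all <- function(models_a, models_b, genome_a, genome_b, orthologs,
                       cfg = pipeline_config(), verbose = FALSE) {
  if (nrow(orthologs) == 0L) stop("empty ortholog table")
  out <- empty_events()
  by_tid_a <- stats::setNames(models_a,
                              vapply(models_a, `[[`, character(1),
                                     "transcript_id"))
  by_tid_b <- stats::setNames(models_b,
                              vapply(models_b, `[[`, character(1),
                                     "transcript_id"))
  for (i in seq_len(nrow(orthologs))) {
    ga <- orthologs$gene_a[i]; gb <- orthologs$gene_b[i]
    if (!ga %in% names(by_tid_a)) {
      if (verbose) message("SKIP_NO_MODEL_A\t", ga)
      next
    }
    if (!gb %in% names(by_tid_b)) {
      if (verbose) message("SKIP_NO_MODEL_B\t", gb)
      next
    }
    ev <- detect_pair(by_tid_a[[ga]], by_tid_b[[gb]], genome_a, genome_b, cfg)
    out <- rbind(out, ev)
  }
  class(out) <- c("loss_events", "data.frame")
  out
}

#' Run the full pipeline from files
#'
#' Reads both genomes and annotations, the ortholog table, and optional
#' support/genotype tables; detects and classifies events for every
#' ortholog pair; applies read-support filters and the fixation survey when
#' the corresponding tables are supplied; writes `events.tsv`,
#' `summary.json` and `config.json` into `out_dir` when given.
#' Re-running with identical inputs produces byte-identical outputs.
#'
#' @param genome_a,genome_b FASTA paths (donor-candidate species first).
#' @param gff_a,gff_b GFF3 paths.
#' @param orthologs TSV path with columns gene_a, gene_b (transcript ids).
#' @param support,genotypes Optional TSV paths (see
#'   [read_support_table()], [read_genotype_table()]).
#' @param out_dir Optional output directory.
#' @param cfg A [pipeline_config()].
#' @param verbose Log skipped pairs with reason codes to stderr.
#' @return Object of class `intronloss_result`: events, fixation, summary.
#' @export
run_pipeline <- function(genome_a, gff_a, genome_b, gff_b, orthologs,
                         support = NULL, genotypes = NULL, out_dir = NULL,
                         cfg = pipeline_config(), verbose = FALSE) {
  for (f in c(genome_a, gff_a, genome_b, gff_b, orthologs))
    if (!file.exists(f)) stop("unreadable input: ", f)
  ga <- load_genome(genome_a)
  gb <- load_genome(genome_b)
  ma <- primary_transcripts(load_gene_models(gff_a))
  mb <- primary_transcripts(load_gene_models(gff_b))
  orth <- utils::read.delim(orthologs, stringsAsFactors = FALSE)
  if (nrow(orth) == 0L) stop("empty ortholog table: ", orthologs)
  events <- detect_all(ma, mb, ga, gb, orth, cfg, verbose = verbose)
  if (!is.null(support))
    events <- apply_support_filters(events, read_support_table(support),
                                    cfg$thresholds)
  fixation <- if (!is.null(genotypes))
    fixation_survey_all(read_genotype_table(genotypes)) else NULL
  summ <- summarize(events, fixation = fixation)
  res <- structure(list(events = events, fixation = fixation,
                        summary = summ, config = cfg),
                   class = "intronloss_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_event_table(events, file.path(out_dir, "events.tsv"))
    jsonlite::write_json(summary_to_list(summ),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(
      list(W = cfg$W, tol = cfg$tol,
           adjacency_window = cfg$adjacency_window,
           rna_strictly_greater_than = cfg$thresholds$rna_strictly_greater_than,
           wgs_min = cfg$thresholds$wgs_min,
           retention_identity = cfg$retention_identity,
           retention_coverage = cfg$retention_coverage,
           q = cfg$q, seed = cfg$seed,
           match = cfg$params$match, mismatch = cfg$params$mismatch,
           gap_open = cfg$params$gap_open,
           gap_extend = cfg$params$gap_extend),
      file.path(out_dir, "config.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

EVENT_TSV_COLUMNS <- c("donor_gene", "recipient_gene", "intron_index",
                       "type", "lost_intron_length", "up_indel_bp",
                       "down_indel_bp", "whole_exon_lost_bp", "retention",
                       "direction", "frame_disrupting")

#' Write the event table
#'
#' One row per event, tab-separated, with exactly the standard columns.
#'
#' @param events `loss_events` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events[, EVENT_TSV_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table
#'
#' @param path TSV path written by [write_event_table()].
#' @return data.frame.
#' @export
read_event_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

EVENT_TYPES <- c("PIL", "IIL", "DE_INTRONIZATION", "DE_EXONIZATION",
                 "EXON_DELETION", "CANDIDATE_GAIN",
                 "UNCLASSIFIED_CONVERSION")

#' Summarize an event set
#'
#' Tabulates events by type (total = sum of per-type counts), plus
#' supported/insufficient tallies when read support has been applied and
#' fixed/polymorphic tallies when a fixation survey is attached.
#'
#' @param events A `loss_events` data.frame, or a named count vector such
#'   as `c(PIL = 11, IIL = 6, DE_EXONIZATION = 1, EXON_DELETION = 1)`.
#' @param fixation Optional output of [fixation_survey_all()].
#' @param bias Optional [bias_summary()].
#' @return Object of class `intronloss_summary`.
#' @export
summarize <- function(events, fixation = NULL, bias = NULL) {
  if (is.data.frame(events)) {
    counts <- vapply(EVENT_TYPES, function(ty) sum(events$type == ty),
                     integer(1))
    support <- if ("support" %in% names(events))
      c(supported = sum(events$support == "supported"),
        insufficient = sum(events$support == "insufficient")) else NULL
  } else {
    counts <- stats::setNames(integer(length(EVENT_TYPES)), EVENT_TYPES)
    bad <- setdiff(names(events), EVENT_TYPES)
    if (length(bad)) stop("unknown event type in counts: ", bad[1L])
    counts[names(events)] <- as.integer(events)
    support <- NULL
  }
  fix <- if (!is.null(fixation))
    c(fixed = sum(fixation$status == "fixed"),
      polymorphic = sum(fixation$status == "polymorphic"),
      no_data = sum(fixation$status == "no_data")) else NULL
  structure(list(counts = counts, total = sum(counts), support = support,
                 fixation = fix, bias = bias),
            class = "intronloss_summary")
}

summary_to_list <- function(s) {
  out <- list(counts = as.list(s$counts), total = s$total)
  if (!is.null(s$support)) out$support <- as.list(s$support)
  if (!is.null(s$fixation)) out$fixation <- as.list(s$fixation)
  if (!is.null(s$bias)) {
    b <- s$bias
    out$bias <- list(threshold = b$threshold,
                     counts = b$counts,
                     pearson_chi2 = b$test$pearson_chi2,
                     pearson_p = b$test$pearson_p,
                     yates_chi2 = b$test$yates_chi2,
                     yates_p = b$test$yates_p,
                     fisher_p = b$test$fisher_p)
  }
  out
}

#' @export
print.intronloss_summary <- function(x, ...) {
  cat("<intronloss_summary>\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    for (ty in names(nz)) cat(sprintf("  %-24s %d\n", ty, nz[[ty]]))
  }
  cat(sprintf("  %-24s %d\n", "total", x$total))
  if (!is.null(x$support))
    cat(sprintf("  supported %d, insufficient %d\n",
                x$support[["supported"]], x$support[["insufficient"]]))
  if (!is.null(x$fixation))
    cat(sprintf("  fixed %d, polymorphic %d, no_data %d\n",
                x$fixation[["fixed"]], x$fixation[["polymorphic"]],
                x$fixation[["no_data"]]))
  if (!is.null(x$bias)) print(x$bias)
  invisible(x)
}

#' @export
print.loss_events <- function(x, ...) {
  cat(sprintf("<loss_events> %d event(s)\n", nrow(x)))
  if (nrow(x))
    print(as.data.frame(x)[, c("donor_gene", "recipient_gene",
                               "intron_index", "type", "lost_intron_length",
                               "up_indel_bp", "down_indel_bp",
                               "whole_exon_lost_bp", "retention")],
          row.names = FALSE)
  invisible(x)
}

#' @export
summary.loss_events <- function(object, ...) summarize(object, ...)
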