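#' Project a gene's introns into alignment columns
#'
#' Maps each intron's boundary offset in the spliced sequence to the
#' alignment boundary reached after consuming that many ungapped characters
#' of the gene's alignment row.  Boundaries are in `[0, n_columns]`; the
#' intron sits between columns `boundary` and `boundary + 1`, and the
#' minimal such boundary is used when gap columns abut the site.
#'
#' @param gene A `gene_model`.
#' @param genome Genome vector (used to derive phase/context).
#' @param aln `pairwise_alignment` whose row `row` strips to the gene's
#'   spliced sequence.
#' @param row `"a"` or `"b"`.
#' @param region `"transcript"` or `"cds"`: which spliced sequence was
#'   aligned.  With `"cds"`, only CDS-context introns are placed.
#' @return data.frame: intron_index, column, phase, context, length,
#'   start, end (genomic).
#' @export
project_introns <- function(gene, genome, aln, row = c("a", "b"),
                            region = c("transcript", "cds")) {
  row <- match.arg(row)
  region <- match.arg(region)
  gapped <- if (row == "a") aln$gapped_a else aln$gapped_b
  stripped <- gsub("-", "", gapped, fixed = TRUE)
  spliced <- spliced_sequence(gene, genome, region)
  if (!identical(stripped, spliced))
    stop("alignment row ", row, " does not strip to the spliced ",
         region, " sequence of ", gene$transcript_id)

  introns <- introns_of(gene, genome)
  if (region == "cds") introns <- introns[introns$context == "CDS", ,
                                          drop = FALSE]
  if (nrow(introns) == 0L)
    return(data.frame(intron_index = integer(0), column = integer(0),
                      phase = integer(0), context = character(0),
                      length = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))

  offsets <- intron_offsets(gene, region)[introns$index]
  if (any(offsets > nchar(spliced)))
    stop("intron offset beyond spliced sequence length")
  ch <- strsplit(gapped, "", fixed = TRUE)[[1L]]
  consumed <- cumsum(ch != "-")
  # minimal boundary k with consumed[1..k] == offset
  cols <- vapply(offsets, function(o) {
    if (o == 0L) 0L else match(o, consumed)
  }, integer(1))
  data.frame(intron_index = introns$index, column = cols,
             phase = introns$phase, context = introns$context,
             length = introns$length, start = introns$start,
             end = introns$end, stringsAsFactors = FALSE)
}

# Spliced-coordinate offset of each intron boundary (all introns, indexed
# by intron ordinal).  For region "cds" the offset is in CDS coordinates;
# UTR introns get NA there.
intron_offsets <- function(gene, region = "transcript") {
  ex <- gene$exons
  n <- nrow(ex)
  if (n < 2L) return(integer(0))
  if (region == "transcript") {
    cumsum(ex[, "end"] - ex[, "start"])[seq_len(n - 1L)]
  } else {
    cds <- gene$cds
    cdsw <- cds[, "end"] - cds[, "start"]
    host <- vapply(seq_len(nrow(cds)), function(j)
      which(cds[j, "start"] >= ex[, "start"] &
            cds[j, "end"] <= ex[, "end"])[1L], integer(1))
    vapply(seq_len(n - 1L), function(k) {
      up <- sum(cdsw[host <= k])
      if (up == 0L || up == sum(cdsw)) NA_integer_ else as.integer(up)
    }, integer(1))
  }
}

#' Match intron placements across an ortholog pair
#'
#' Greedy left-to-right one-to-one matching: each placement of `pA` is
#' paired with the nearest unmatched placement of `pB` within `tol`
#' columns (ties broken toward the smaller column), provided the phases
#' are compatible (phase is compared only when both introns are
#' CDS-context with known phase).
#'
#' @param pA,pB data.frames from [project_introns()], sorted by column.
#' @param tol Maximum column difference for homologous positions.
#' @return List of class `structural_diff`: `matched` (data.frame of index
#'   and column pairs), `only_in_a`, `only_in_b` (unmatched placements).
#' @export
diff_structures <- function(pA, pB, tol = 0L) {
  usedB <- rep(FALSE, nrow(pB))
  m_ia <- integer(0); m_ib <- integer(0)
  for (i in seq_len(nrow(pA))) {
    cand <- which(!usedB & abs(pB$column - pA$column[i]) <= tol)
    if (length(cand) && tol > 0L) {
      # phase gates near matches only; at tol = 0 the exact column is the
      # evidence, and an upstream frame-disrupting loss legitimately
      # shifts every downstream phase
      compat <- vapply(cand, function(j) {
        if (identical(pA$context[i], "CDS") && identical(pB$context[j], "CDS") &&
            !is.na(pA$phase[i]) && !is.na(pB$phase[j]))
          pA$phase[i] == pB$phase[j] else TRUE
      }, logical(1))
      cand <- cand[compat]
    }
    if (length(cand)) {
      d <- abs(pB$column[cand] - pA$column[i])
      best <- cand[order(d, pB$column[cand])][1L]
      usedB[best] <- TRUE
      m_ia <- c(m_ia, i); m_ib <- c(m_ib, best)
    }
  }
  structure(list(
    matched = data.frame(index_a = pA$intron_index[m_ia],
                         index_b = pB$intron_index[m_ib],
                         column_a = pA$column[m_ia],
                         column_b = pB$column[m_ib]),
    only_in_a = pA[setdiff(seq_len(nrow(pA)), m_ia), , drop = FALSE],
    only_in_b = pB[!usedB, , drop = FALSE]),
    class = "structural_diff")
}

#' @export
print.structural_diff <- function(x, ...) {
  cat(sprintf("<structural_diff> %d matched, %d only in A, %d only in B\n",
              nrow(x$matched), nrow(x$only_in_a), nrow(x$only_in_b)))
  invisible(x)
}

#' Gap-tolerant retention check of a query inside a locus
#'
#' Declares the query `"retained"` if its best local alignment inside the
#' locus reaches at least `min_identity` over at least `min_coverage` of the
#' query length, `"absent"` otherwise, and `"unknown"` for queries shorter
#' than 10 bp (too short to call).
#'
#' @param query DNA string (>= 10 bp for a call).
#' @param locus DNA string to search within.
#' @param min_identity Identity floor over the aligned region (default 0.70,
#'   deliberately loose: retained intronic/exonic sequence diverges fast).
#' @param min_coverage Minimum aligned fraction of the query (default 0.70).
#' @return One of `"retained"`, `"absent"`, `"unknown"`.
#' @export
check_genomic_retention <- function(query, locus,
                                    min_identity = 0.70,
                                    min_coverage = 0.70) {
  if (nchar(query) < 10L) return("unknown")
  if (nchar(locus) < 1L) return("absent")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(locus),
    type = "local", substitutionMatrix = sub,
    gapOpening = 10, gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(aln))
  subj <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(pat, "", fixed = TRUE)[[1L]]
  sc <- strsplit(subj, "", fixed = TRUE)[[1L]]
  ncol_aln <- length(pc)
  if (ncol_aln == 0L) return("absent")
  ident <- sum(pc == sc & pc != "-") / ncol_aln
  coverage <- sum(pc != "-") / nchar(query)
  if (ident >= min_identity && coverage >= min_coverage) "retained" else "absent"
}

#' Classifier configuration
#'
#' @param tol Column tolerance for matching intron positions (default 0:
#'   positions are homologous only if identical).
#' @param adjacency_window Columns on each side of a projected intron site
#'   within which an exonic gap run counts as accompanying the loss
#'   (default 15).
#' @param retention_identity,retention_coverage Thresholds for
#'   [check_genomic_retention()].
#' @param exon_missing_frac Fraction of an exon's columns that must be
#'   gapped in the recipient row to call the whole exon missing
#'   (default 0.8, tolerant of substitution-induced gap sliding).
#' @param deintron_pad Extra bp on each side of the projected site searched
#'   for a retained intron inside the recipient spliced transcript.
#' @param locus_margin Genomic bp added on each side of the recipient gene
#'   span for retention checks.
#' @return List of class `classify_config`.
#' @export
classify_config <- function(tol = 0L, adjacency_window = 15L,
                            retention_identity = 0.70,
                            retention_coverage = 0.70,
                            exon_missing_frac = 0.8,
                            deintron_pad = 50L,
                            locus_margin = 2000L) {
  structure(list(tol = tol, adjacency_window = adjacency_window,
                 retention_identity = retention_identity,
                 retention_coverage = retention_coverage,
                 exon_missing_frac = exon_missing_frac,
                 deintron_pad = deintron_pad,
                 locus_margin = locus_margin),
            class = "classify_config")
}

empty_events <- function() {
  data.frame(event_id = character(0), donor_gene = character(0),
             recipient_gene = character(0), intron_index = integer(0),
             type = character(0), lost_intron_length = integer(0),
             up_indel_bp = integer(0), down_indel_bp = integer(0),
             whole_exon_lost_bp = integer(0), retention = character(0),
             direction = character(0), frame_disrupting = logical(0),
             context = character(0), donor_offset = integer(0),
             stringsAsFactors = FALSE)
}

event_row <- function(donor, recipient, intron_index, type,
                      lost_intron_length = 0L, up = 0L, down = 0L,
                      whole_exon = 0L, retention = "unknown",
                      context = "CDS", frame_disrupting = FALSE,
                      donor_offset = NA_integer_) {
  data.frame(
    event_id = paste(donor$transcript_id, intron_index, type, sep = ":"),
    donor_gene = donor$transcript_id,
    recipient_gene = recipient$transcript_id,
    intron_index = as.integer(intron_index), type = type,
    lost_intron_length = as.integer(lost_intron_length),
    up_indel_bp = as.integer(up), down_indel_bp = as.integer(down),
    whole_exon_lost_bp = as.integer(whole_exon),
    retention = retention, direction = "unpolarized",
    frame_disrupting = frame_disrupting, context = context,
    donor_offset = as.integer(donor_offset), stringsAsFactors = FALSE)
}

# Maximal runs of columns gapped in either alignment row.
gap_runs <- function(aln) {
  ch <- aln_chars(aln)
  g <- ch$a == "-" | ch$b == "-"
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Recipient-row spliced offset reached at an alignment boundary.
row_offset_at <- function(gapped, boundary) {
  if (boundary == 0L) return(0L)
  ch <- strsplit(gapped, "", fixed = TRUE)[[1L]]
  sum(ch[seq_len(boundary)] != "-")
}

#' Classify structural differences between an ortholog pair
#'
#' Applies the five-type event taxonomy to every unmatched donor intron and
#' every missing donor internal exon, using the alignment, retention checks
#' against the recipient genome, and exonic gap runs near the projected
#' intron site.  Types:
#' \describe{
#'   \item{PIL}{precise intron loss: intron absent, flanking exons intact.}
#'   \item{IIL}{imprecise intron loss: intron absent with exonic indels
#'     (possibly a whole adjacent exon, reported in `whole_exon_lost_bp`).}
#'   \item{DE_INTRONIZATION}{intron sequence retained inside the recipient's
#'     spliced transcript (splice signals dead, no genomic deletion).}
#'   \item{DE_EXONIZATION}{internal exon converted into intron interior;
#'     exon sequence retained in the recipient genome.}
#'   \item{EXON_DELETION}{internal exon deleted from the genome, the two
#'     flanking introns fused.}
#'   \item{CANDIDATE_GAIN}{unmatched recipient intron, flagged but not
#'     further classified.}
#'   \item{UNCLASSIFIED_CONVERSION}{intron absent from the transcript but
#'     retained in the recipient genome without fitting the above; flagged.}
#' }
#'
#' @param diff `structural_diff` from [diff_structures()].
#' @param aln The `pairwise_alignment` the diff was derived from (donor in
#'   row a, recipient in row b).
#' @param donor,recipient `gene_model`s (donor = intron-bearing reference).
#' @param genome_donor,genome_recipient Genome vectors.
#' @param cfg A [classify_config()].
#' @param region Spliced region compared (`"transcript"` or `"cds"`).
#' @return data.frame of events (class `loss_events`), one row per
#'   unmatched donor intron or flagged record.
#' @export
classify_events <- function(diff, aln, donor, recipient,
                            genome_donor, genome_recipient,
                            cfg = classify_config(),
                            region = "transcript") {
  events <- empty_events()
  pA_un <- diff$only_in_a
  introns_d <- introns_of(donor, genome_donor)
  offsets_d <- intron_offsets(donor, region)
  ch <- aln_chars(aln)
  runs <- gap_runs(aln)
  gap_a <- ch$a == "-"; gap_b <- ch$b == "-"

  # recipient genomic locus for retention checks
  rspan <- range(c(recipient$exons[, "start"], recipient$exons[, "end"]))
  rchrom_len <- nchar(genome_recipient[[recipient$chrom]])
  locus <- seq_region(genome_recipient, recipient$chrom,
                      max(0L, rspan[1L] - cfg$locus_margin),
                      min(rchrom_len, rspan[2L] + cfg$locus_margin),
                      recipient$strand)
  recip_spliced <- spliced_sequence(recipient, genome_recipient, region)

  retention <- function(q) check_genomic_retention(
    q, locus, cfg$retention_identity, cfg$retention_coverage)

  donor_intron_seq <- function(k) {
    i <- introns_d[introns_d$index == k, ]
    seq_region(genome_donor, donor$chrom,
               min(i$start, i$end), max(i$start, i$end),
               donor$strand)
  }

  # columns occupied by each donor exon (donor-row positions), in the
  # coordinate system of the aligned region (transcript or CDS)
  donor_pos_col <- which(!gap_a)               # column of donor position p
  exw <- exon_spliced_widths(donor, region)
  excum <- c(0L, cumsum(exw))
  exon_cols <- function(k) {
    if (exw[k] == 0L) return(integer(0))       # exon absent from this region
    s <- excum[k] + 1L; e <- excum[k + 1L]
    if (e > length(donor_pos_col)) return(integer(0))
    donor_pos_col[s:e]
  }

  consumed_introns <- integer(0)

  # ---- exon-level pass: missing internal donor exons --------------------
  n_ex <- nrow(donor$exons)
  if (n_ex >= 3L) {
    matched_a <- diff$matched$index_a
    for (k in 2L:(n_ex - 1L)) {
      cols <- exon_cols(k)
      if (length(cols) == 0L) next
      frac_gone <- mean(gap_b[cols])
      if (frac_gone < cfg$exon_missing_frac) next
      fl <- c(k - 1L, k)                      # flanking donor intron indices
      fl_unmatched <- fl[!(fl %in% matched_a)]
      fl_matched <- fl[fl %in% matched_a]
      if (length(fl_unmatched) != 1L || length(fl_matched) != 1L) next
      if (fl_unmatched %in% consumed_introns) next

      exseq <- seq_region(genome_donor, donor$chrom,
                          donor$exons[k, "start"], donor$exons[k, "end"],
                          donor$strand)
      exlen <- donor$exons[k, "end"] - donor$exons[k, "start"]
      iun <- fl_unmatched
      iun_len <- introns_d$length[introns_d$index == iun]
      ctx <- exon_context(donor, k)
      frame_bad <- identical(ctx, "CDS") && (exlen %% 3L != 0L)
      anchor <- pA_un$column[match(iun, pA_un$intron_index)]
      if (is.na(anchor)) {
        # unmatched intron bookkeeping out of sync; skip to intron pass
        next
      }

      ex_ret <- retention(exseq)
      if (ex_ret == "retained") {
        # fusion events are reported under the donor intron that follows
        # the exon (ordinal k), a fixed convention independent of which
        # flanking intron the matcher happened to pair
        ev <- event_row(donor, recipient, k, "DE_EXONIZATION",
                        lost_intron_length = introns_d$length[
                          introns_d$index == k],
                        whole_exon = exlen, retention = "retained",
                        context = ctx, frame_disrupting = frame_bad,
                        donor_offset = offsets_d[k])
      } else {
        ret_un <- retention(donor_intron_seq(iun))
        ret_ma <- retention(donor_intron_seq(fl_matched))
        if (ret_un == "retained" && ret_ma == "retained") {
          ev <- event_row(donor, recipient, k, "EXON_DELETION",
                          lost_intron_length = 0L,
                          whole_exon = exlen, retention = "absent",
                          context = ctx, frame_disrupting = frame_bad,
                          donor_offset = offsets_d[k])
        } else {
          # exon lost together with one intron, the other intron intact:
          # the lost intron is the flanking intron whose sequence is
          # absent from the recipient locus (the retained one survives,
          # even though the matcher may have paired it under the other
          # donor ordinal)
          lost_k <- if (ret_un == "absent" || ret_ma == "retained")
            iun else fl_matched
          if (ret_un == "retained" && ret_ma == "absent") lost_k <- fl_matched
          lost_len <- introns_d$length[introns_d$index == lost_k]
          extra <- extra_indels_near(runs, gap_a, gap_b, cols, anchor,
                                     cfg$adjacency_window)
          ev <- event_row(donor, recipient, lost_k, "IIL",
                          lost_intron_length = lost_len,
                          up = extra["up"], down = extra["down"],
                          whole_exon = exlen, retention = "absent",
                          context = ctx, frame_disrupting = frame_bad,
                          donor_offset = offsets_d[lost_k])
        }
      }
      events <- rbind(events, ev)
      consumed_introns <- c(consumed_introns, iun)
    }
  }

  # ---- intron-level pass ------------------------------------------------
  for (r in seq_len(nrow(pA_un))) {
    k <- pA_un$intron_index[r]
    if (k %in% consumed_introns) next
    anchor <- pA_un$column[r]
    L <- pA_un$length[r]
    ctx <- pA_un$context[r]
    iseq <- donor_intron_seq(k)

    # (1) intron retained inside the recipient's spliced transcript?
    q <- row_offset_at(aln$gapped_b, anchor)
    win_s <- max(0L, q - L - cfg$deintron_pad)
    win_e <- min(nchar(recip_spliced), q + L + cfg$deintron_pad)
    near <- substr(recip_spliced, win_s + 1L, win_e)
    if (nchar(near) >= 1L &&
        check_genomic_retention(iseq, near, cfg$retention_identity,
                                cfg$retention_coverage) == "retained") {
      events <- rbind(events, event_row(
        donor, recipient, k, "DE_INTRONIZATION",
        lost_intron_length = L, retention = "retained", context = ctx,
        frame_disrupting = identical(ctx, "CDS") && (L %% 3L != 0L),
        donor_offset = offsets_d[k]))
      next
    }

    # (2) retained in the recipient genomic locus -> flagged conversion
    if (retention(iseq) == "retained") {
      events <- rbind(events, event_row(
        donor, recipient, k, "UNCLASSIFIED_CONVERSION",
        lost_intron_length = L, retention = "retained", context = ctx,
        donor_offset = offsets_d[k]))
      next
    }

    # (3) absent: exonic gap runs near the projected site?
    w <- cfg$adjacency_window
    touching <- runs[runs$start <= anchor + w & runs$end >= anchor - w + 1L, ,
                     drop = FALSE]
    if (nrow(touching) == 0L) {
      events <- rbind(events, event_row(
        donor, recipient, k, "PIL", lost_intron_length = L,
        retention = "absent", context = ctx,
        donor_offset = offsets_d[k]))
    } else {
      up <- 0L; down <- 0L; net <- 0L
      for (t in seq_len(nrow(touching))) {
        cols <- seq.int(touching$start[t], touching$end[t])
        gcols <- cols[gap_a[cols] | gap_b[cols]]
        up <- up + sum(gcols <= anchor)
        down <- down + sum(gcols > anchor)
        net <- net + sum(gap_b[cols]) - sum(gap_a[cols])
      }
      events <- rbind(events, event_row(
        donor, recipient, k, "IIL", lost_intron_length = L,
        up = up, down = down, retention = "absent", context = ctx,
        frame_disrupting = identical(ctx, "CDS") && (net %% 3L != 0L),
        donor_offset = offsets_d[k]))
    }
  }

  # ---- unmatched recipient introns -> candidate gains -------------------
  pB_un <- diff$only_in_b
  for (r in seq_len(nrow(pB_un))) {
    events <- rbind(events, data.frame(
      event_id = paste(recipient$transcript_id, pB_un$intron_index[r],
                       "CANDIDATE_GAIN", sep = ":"),
      donor_gene = donor$transcript_id,
      recipient_gene = recipient$transcript_id,
      intron_index = pB_un$intron_index[r], type = "CANDIDATE_GAIN",
      lost_intron_length = pB_un$length[r], up_indel_bp = 0L,
      down_indel_bp = 0L, whole_exon_lost_bp = 0L, retention = "unknown",
      direction = "unpolarized", frame_disrupting = FALSE,
      context = pB_un$context[r], donor_offset = NA_integer_,
      stringsAsFactors = FALSE))
  }

  class(events) <- c("loss_events", "data.frame")
  events
}

# bp each exon contributes to the aligned spliced region
exon_spliced_widths <- function(gene, region) {
  ex <- gene$exons
  if (region == "transcript" || nrow(gene$cds) == 0L)
    return(ex[, "end"] - ex[, "start"])
  vapply(seq_len(nrow(ex)), function(k) {
    ov <- pmin(gene$cds[, "end"], ex[k, "end"]) -
          pmax(gene$cds[, "start"], ex[k, "start"])
    sum(pmax(0L, ov))
  }, numeric(1))
}

# context of a donor exon: CDS if it holds any CDS bp, else UTR5/UTR3
exon_context <- function(gene, k) {
  if (nrow(gene$cds) == 0L) return("CDS")
  ex <- gene$exons[k, ]
  has_cds <- any(gene$cds[, "start"] < ex["end"] &
                 gene$cds[, "end"] > ex["start"])
  if (has_cds) return("CDS")
  # before first CDS exon (coding order) => 5'UTR, else 3'UTR
  host_first <- which(gene$exons[, "start"] <= min(gene$cds[, "start"]) &
                      gene$exons[, "end"] >= min(gene$cds[, "start"]))[1L]
  first_cds_exon <- if (gene$strand == "+") {
    which(gene$cds[1L, "start"] >= gene$exons[, "start"] &
          gene$cds[1L, "end"] <= gene$exons[, "end"])[1L]
  } else host_first
  if (k < first_cds_exon) "UTR5" else "UTR3"
}

# gap columns in runs touching the window, excluding those of `exon_cols`
extra_indels_near <- function(runs, gap_a, gap_b, exon_cols, anchor, w) {
  up <- 0L; down <- 0L
  touching <- runs[runs$start <= anchor + w & runs$end >= anchor - w + 1L, ,
                   drop = FALSE]
  for (t in seq_len(nrow(touching))) {
    cols <- seq.int(touching$start[t], touching$end[t])
    cols <- setdiff(cols[gap_a[cols] | gap_b[cols]], exon_cols)
    up <- up + sum(cols <= anchor)
    down <- down + sum(cols > anchor)
  }
  c(up = up, down = down)
}

#' Polarize loss events with an outgroup
#'
#' An event becomes a polarized loss in the recipient lineage when the
#' outgroup carries an intron at the homologous position (within `tol` of
#' the donor-spliced offset); otherwise it stays unpolarized (a gain in
#' the donor lineage is the parsimonious alternative when the outgroup
#' also lacks the intron).
#'
#' @param events `loss_events` data.frame.
#' @param outgroup_offsets Integer vector of outgroup intron boundary
#'   offsets projected into donor spliced coordinates (see
#'   [project_outgroup_offsets()]), or `NULL` when no outgroup exists.
#' @param tol Offset tolerance in bp.
#' @return `events` with the `direction` column updated.
#' @export
polarize <- function(events, outgroup_offsets = NULL, tol = 0L) {
  if (is.null(outgroup_offsets) || nrow(events) == 0L) return(events)
  loss_types <- c("PIL", "IIL", "DE_INTRONIZATION", "DE_EXONIZATION",
                  "EXON_DELETION")
  for (r in seq_len(nrow(events))) {
    if (!events$type[r] %in% loss_types) next
    o <- events$donor_offset[r]
    if (!is.na(o) && any(abs(outgroup_offsets - o) <= tol))
      events$direction[r] <- "polarized_loss"
  }
  events
}

#' Project outgroup intron positions into donor spliced coordinates
#'
#' Aligns the outgroup spliced sequence to the donor's and converts each
#' outgroup intron boundary into the donor-row offset at the same
#' alignment boundary.
#'
#' @param donor,outgroup `gene_model`s.
#' @param genome_donor,genome_outgroup Genome vectors.
#' @param params [alignment_params()].
#' @param region Spliced region to compare.
#' @return Integer vector of donor-spliced offsets.
#' @export
project_outgroup_offsets <- function(donor, outgroup, genome_donor,
                                     genome_outgroup,
                                     params = alignment_params(),
                                     region = "transcript") {
  aln <- global_align(spliced_sequence(donor, genome_donor, region),
                      spliced_sequence(outgroup, genome_outgroup, region),
                      params)
  po <- project_introns(outgroup, genome_outgroup, aln, row = "b",
                        region = region)
  vapply(po$column, function(col) row_offset_at(aln$gapped_a, col),
         integer(1))
}
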