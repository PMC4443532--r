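#' Read-support thresholds
#'
#' A candidate event is supported when the relevant splice junction has
#' strictly more than `rna_strictly_greater_than` RNA-Seq reads AND the
#' variation site is covered by at least `wgs_min` whole-genome shotgun
#' reads.  The RNA threshold (> 10) follows the evidence rule used for the
#' worked examples; the WGS minimum of 5 is a configurable convention (a
#' site with nine WGS reads was accepted, no cutoff was stated).
#'
#' @param rna_strictly_greater_than RNA-Seq junction read threshold
#'   (strict inequality), default 10.
#' @param wgs_min Minimum WGS reads at the variation site, default 5.
#' @return List of class `support_thresholds`.
#' @export
support_thresholds <- function(rna_strictly_greater_than = 10L,
                               wgs_min = 5L) {
  if (rna_strictly_greater_than < 0L || wgs_min < 0L)
    stop("thresholds must be non-negative")
  structure(list(rna_strictly_greater_than = as.integer(rna_strictly_greater_than),
                 wgs_min = as.integer(wgs_min)),
            class = "support_thresholds")
}

#' Read a support table
#'
#' TSV with columns target_id, source (`rna_junction`, `wgs_site`, `est`)
#' and read_count.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_support_table <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_id", "source", "read_count")
  if (!all(need %in% names(s)))
    stop("support table must have columns: ", paste(need, collapse = ", "))
  s
}

#' Annotate events with read support
#'
#' Adds a `support` column (`"supported"` / `"insufficient"`).  An event is
#' supported iff its RNA junction count strictly exceeds the RNA threshold
#' and its WGS site count meets the WGS minimum; missing records count as 0.
#'
#' @param events `loss_events` data.frame with an `event_id` column.
#' @param support data.frame with target_id, source, read_count.
#' @param thresholds A [support_thresholds()] object.
#' @return `events` with the `support` column added.
#' @export
apply_support_filters <- function(events, support,
                                  thresholds = support_thresholds()) {
  if (any(support$read_count < 0))
    stop("negative read counts in support table")
  if (anyDuplicated(support[c("target_id", "source")]))
    stop("duplicate (target_id, source) pair in support table")
  count_for <- function(id, src) {
    hit <- support$read_count[support$target_id == id & support$source == src]
    if (length(hit)) hit[1L] else 0L
  }
  rna <- vapply(events$event_id, count_for, numeric(1), src = "rna_junction")
  wgs <- vapply(events$event_id, count_for, numeric(1), src = "wgs_site")
  events$support <- ifelse(rna > thresholds$rna_strictly_greater_than &
                           wgs >= thresholds$wgs_min,
                           "supported", "insufficient")
  events
}

#' Read a genotype table
#'
#' TSV with columns event_id, line_id, state (carrier / non_carrier /
#' missing).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_genotype_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "line_id", "state")
  if (!all(need %in% names(g)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(g$state), c("carrier", "non_carrier", "missing"))
  if (length(bad)) stop("unknown genotype state: ", bad[1L])
  g
}

#' Fixation survey of one event across population lines
#'
#' The allele frequency is carriers / called lines (missing lines are
#' excluded from the denominator).  An event is `fixed` when every called
#' line carries the allele and at least two lines were called; otherwise it
#' is `polymorphic`, or `no_data` when no line could be called.
#'
#' @param states Character vector of per-line states (`carrier`,
#'   `non_carrier`, `missing`), or a data.frame with a `state` column.
#' @return Object of class `fixation_result`: allele_frequency, n_called,
#'   carriers, status.
#' @export
fixation_survey <- function(states) {
  if (is.data.frame(states)) states <- states$state
  if (length(states) < 1L) stop("at least one line required")
  bad <- setdiff(unique(states), c("carrier", "non_carrier", "missing"))
  if (length(bad)) stop("unknown genotype state: ", bad[1L])
  carriers <- sum(states == "carrier")
  n_called <- carriers + sum(states == "non_carrier")
  if (n_called == 0L) {
    return(structure(list(allele_frequency = NA_real_, n_called = 0L,
                          carriers = 0L, status = "no_data"),
                     class = "fixation_result"))
  }
  freq <- carriers / n_called
  status <- if (n_called >= 2L && carriers == n_called) "fixed"
            else "polymorphic"
  structure(list(allele_frequency = freq, n_called = n_called,
                 carriers = carriers, status = status),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  if (x$status == "no_data") {
    cat("<fixation_result> no_data (0 lines called)\n")
  } else {
    cat(sprintf("<fixation_result> %s: %d/%d carriers, frequency %.1f%%\n",
                x$status, x$carriers, x$n_called,
                100 * x$allele_frequency))
  }
  invisible(x)
}

#' Fixation survey over a whole genotype table
#'
#' @param genotypes data.frame with event_id, line_id, state.
#' @return data.frame: event_id, carriers, n_called, allele_frequency,
#'   frequency_pct (to 0.1%), status.
#' @export
fixation_survey_all <- function(genotypes) {
  ids <- unique(genotypes$event_id)
  rows <- lapply(ids, function(id) {
    fr <- fixation_survey(genotypes$state[genotypes$event_id == id])
    data.frame(event_id = id, carriers = fr$carriers,
               n_called = fr$n_called,
               allele_frequency = fr$allele_frequency,
               frequency_pct = if (is.na(fr$allele_frequency)) NA_character_
                               else sprintf("%.1f", 100 * fr$allele_frequency),
               status = fr$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
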