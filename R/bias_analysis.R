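#' Quantile threshold for alignment filtering
#'
#' q-quantile of a set of alignment identities by linear interpolation
#' between order statistics (index h = (n - 1) q, the type-7 convention),
#' used as an identity floor when screening alignments against a diverged
#' reference genome.
#'
#' @param identities Numeric vector of identities in `[0, 1]`.
#' @param q Quantile, default 0.25 (first quartile).
#' @return Scalar threshold.
#' @export
quartile_threshold <- function(identities, q = 0.25) {
  if (length(identities) == 0L) stop("empty identity list")
  if (any(is.na(identities)) || any(identities < 0 | identities > 1))
    stop("identities must be in [0, 1]")
  unname(stats::quantile(identities, probs = q, type = 7))
}

#' Screen detection records by flank identity
#'
#' Sets `passes_filter` on each record: an event is detectable against the
#' diverged reference only if an ortholog was found AND its flank identity
#' meets the threshold.
#'
#' @param records data.frame with columns event_id, event_type
#'   (`"PIL"`/`"IIL"`), ortholog_found (logical), flank_combined_identity
#'   (numeric, `NA` when no ortholog/alignment exists).
#' @param threshold Identity floor in `[0, 1]`.
#' @return `records` with `passes_filter` (logical) set.
#' @export
screen_events <- function(records, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  records$passes_filter <- records$ortholog_found &
    !is.na(records$flank_combined_identity) &
    records$flank_combined_identity >= threshold
  records
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# every table with the observed margins whose probability does not exceed
# the observed table's probability (within a relative tolerance for
# floating-point safety) contributes to p.
fisher_exact_p <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  ks <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1L, 1L], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Association test for a 2x2 detection table
#'
#' Computes, for a 2x2 table of counts (rows: event types PIL/IIL;
#' columns: detected/undetected), the Pearson chi-square, the
#' Yates-continuity-corrected chi-square (both 1 df), and the two-sided
#' Fisher exact p by hypergeometric enumeration.  All three are reported:
#' with expected cell counts below 5 the exact test is the recommended
#' reference.
#'
#' @param tab 2x2 numeric matrix of non-negative counts; both margins must
#'   be nonzero.
#' @return Object of class `contingency_result`: table, pearson_chi2,
#'   pearson_p, yates_chi2, yates_p, fisher_p.
#' @export
detection_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative cell count")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  pearson <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  yates <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  structure(list(table = tab,
                 pearson_chi2 = unname(pearson$statistic),
                 pearson_p = pearson$p.value,
                 yates_chi2 = unname(yates$statistic),
                 yates_p = yates$p.value,
                 fisher_p = fisher_exact_p(tab)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result> 2x2 detection table\n")
  print(x$table)
  cat(sprintf("  Pearson chi2 = %.4f, p = %.4f\n", x$pearson_chi2, x$pearson_p))
  cat(sprintf("  Yates chi2   = %.4f, p = %.4f\n", x$yates_chi2, x$yates_p))
  cat(sprintf("  Fisher exact p = %.4f (recommended for small cells)\n",
              x$fisher_p))
  invisible(x)
}

#' Detection-bias summary
#'
#' Screens detection records at a threshold, tabulates detected vs
#' undetected counts per event type, and runs [detection_test()] on the
#' resulting 2x2 table.  Percentages are reported to one decimal.
#'
#' @param records See [screen_events()].
#' @param threshold Identity floor.
#' @return List of class `bias_summary`: records, counts (data.frame with
#'   per-type detected/undetected/percent), test (`contingency_result` or
#'   `NULL` when a margin is zero).
#' @export
bias_summary <- function(records, threshold) {
  records <- screen_events(records, threshold)
  types <- c("PIL", "IIL")
  counts <- do.call(rbind, lapply(types, function(ty) {
    sel <- records$event_type == ty
    det <- sum(records$passes_filter[sel])
    tot <- sum(sel)
    data.frame(event_type = ty, detected = det, undetected = tot - det,
               total = tot,
               detected_pct = if (tot > 0) sprintf("%.1f", 100 * det / tot)
                              else NA_character_,
               stringsAsFactors = FALSE)
  }))
  tab <- matrix(c(counts$detected[1L], counts$undetected[1L],
                  counts$detected[2L], counts$undetected[2L]),
                nrow = 2L, byrow = TRUE,
                dimnames = list(types, c("detected", "undetected")))
  test <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NULL
          else detection_test(tab)
  structure(list(records = records, threshold = threshold,
                 counts = counts, test = test),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("<bias_summary> threshold %.3f\n", x$threshold))
  print(x$counts, row.names = FALSE)
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}

#' Fraction detected, printed to one decimal
#'
#' @param detected,total Counts.
#' @return Character scalar like `"23.5"`.
#' @export
detected_percent <- function(detected, total) {
  if (total <= 0) stop("total must be positive")
  sprintf("%.1f", 100 * detected / total)
}
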