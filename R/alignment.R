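#' Alignment scoring parameters
#'
#' Affine-gap scoring: a gap run of length L scores
#' `gap_open + L * gap_extend`.  Defaults (match +2, mismatch -3,
#' open -10, extend -1) are conventional for DNA within a genus.
#'
#' @param match Match score (> mismatch).
#' @param mismatch Mismatch score.
#' @param gap_open Gap-opening penalty (<= gap_extend <= 0).
#' @param gap_extend Per-position gap-extension penalty (<= 0).
#' @return List of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -3,
                             gap_open = -10, gap_extend = -1) {
  if (!(match > mismatch)) stop("match score must exceed mismatch score")
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("require gap_open <= gap_extend <= 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

check_dna <- function(x, what = "sequence") {
  if (grepl("[^ACGTN]", x))
    stop(what, " contains non-DNA characters")
  invisible(x)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap penalties and a
#' fixed, deterministic traceback (tie order diagonal > up > left).
#' Terminal gaps are scored (true global alignment).
#'
#' @param a,b DNA strings (either may be empty).  `N` never matches.
#' @param params An [alignment_params()] object.
#' @return Object of class `pairwise_alignment`: list with `gapped_a`,
#'   `gapped_b`, `score`, `n_columns`, `params`.
#' @export
global_align <- function(a, b, params = alignment_params()) {
  a <- toupper(a); b <- toupper(b)
  check_dna(a, "a"); check_dna(b, "b")
  r <- gotoh_align_cpp(a, b, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  structure(list(gapped_a = r$gapped_a, gapped_b = r$gapped_b,
                 score = r$score, n_columns = nchar(r$gapped_a),
                 params = params),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %g, identity %.3f\n",
              x$n_columns, x$score, alignment_identity(x)))
  if (x$n_columns <= 80) {
    cat(" ", x$gapped_a, "\n ", x$gapped_b, "\n", sep = "")
  }
  invisible(x)
}

aln_chars <- function(aln) {
  list(a = strsplit(aln$gapped_a, "", fixed = TRUE)[[1L]],
       b = strsplit(aln$gapped_b, "", fixed = TRUE)[[1L]])
}

#' Gap-excluded alignment identity
#'
#' Fraction of matching positions among columns with no gap in either row;
#' 0 when no ungapped column exists.
#'
#' @param aln A `pairwise_alignment`.
#' @return Fraction in `[0, 1]`.
#' @export
alignment_identity <- function(aln) {
  ch <- aln_chars(aln)
  ok <- ch$a != "-" & ch$b != "-"
  if (!any(ok)) return(0)
  sum(ch$a[ok] == ch$b[ok] & ch$a[ok] != "N") / sum(ok)
}

#' Gap-excluded flank identity around an event site
#'
#' Walking outward from an anchor boundary, counts on each side the first
#' `W` alignment columns that are ungapped in both rows (gap columns are
#' skipped, not counted) and reports the fraction of matches among them.
#' The anchor is a boundary in `[0, n_columns]`: columns `<= anchor` are
#' the left flank, columns `> anchor` the right flank.
#'
#' @param aln A `pairwise_alignment`.
#' @param anchor_column Boundary in `[0, n_columns]`.
#' @param W Window width in counted (ungapped) positions per side; 45 by
#'   default, the standard flank width for this analysis.
#' @return Object of class `flank_identity`: anchor_column,
#'   left_identity, right_identity, combined_identity, counted_left,
#'   counted_right, matches_left, matches_right.
#' @export
flank_identity <- function(aln, anchor_column, W = 45L) {
  n <- aln$n_columns
  if (anchor_column < 0L || anchor_column > n)
    stop("anchor_column outside alignment: ", anchor_column)
  ch <- aln_chars(aln)
  ungapped <- ch$a != "-" & ch$b != "-"
  matches <- ungapped & ch$a == ch$b & ch$a != "N"

  take <- function(cols) {
    cols <- cols[ungapped[cols]]
    cols <- cols[seq_len(min(W, length(cols)))]
    c(counted = length(cols), matched = sum(matches[cols]))
  }
  left <- if (anchor_column >= 1L) take(rev(seq_len(anchor_column)))
          else c(counted = 0L, matched = 0L)
  right <- if (anchor_column < n) take(seq.int(anchor_column + 1L, n))
           else c(counted = 0L, matched = 0L)

  ratio <- function(m, c) if (c > 0L) m / c else NA_real_
  tot <- left[["counted"]] + right[["counted"]]
  structure(list(
    anchor_column = anchor_column,
    left_identity = ratio(left[["matched"]], left[["counted"]]),
    right_identity = ratio(right[["matched"]], right[["counted"]]),
    combined_identity = if (tot > 0L)
      (left[["matched"]] + right[["matched"]]) / tot else NA_real_,
    counted_left = left[["counted"]], counted_right = right[["counted"]],
    matches_left = left[["matched"]], matches_right = right[["matched"]]),
    class = "flank_identity")
}

#' @export
print.flank_identity <- function(x, ...) {
  cat(sprintf(
    "<flank_identity> anchor %d: left %.3f (%d), right %.3f (%d), combined %.3f\n",
    x$anchor_column, x$left_identity, x$counted_left,
    x$right_identity, x$counted_right, x$combined_identity))
  invisible(x)
}
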