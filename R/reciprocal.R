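# Reciprocal-translocation balance arithmetic.
#
# With both partner genes on the plus strand, the forward derivative
# retains chr22 bases up to pos22_fwd and chr9 bases from pos9_fwd on,
# while the reciprocal derivative retains chr9 bases up to pos9_rec and
# chr22 bases from pos22_rec on. Bases present on neither derivative
# are deleted; bases present on both are duplicated:
#
#   delta22 = pos22_rec - pos22_fwd - 1   (chr22 bases lost if > 0,
#                                          duplicated if < 0)
#   delta9  = pos9_fwd  - pos9_rec  - 1
#
# so adjacency (pos22_rec = pos22_fwd + 1, pos9_fwd = pos9_rec + 1)
# is the perfectly balanced case: every base on exactly one derivative.

#' Create a breakpoint pair
#'
#' @param pos22,pos9 0-based coordinates (see
#'   [breakpoint_coordinates] for which junction base each one names).
#' @param kind `"forward"` (BCR::ABL1 analog) or `"reciprocal"`
#'   (ABL1::BCR analog).
#' @return an object of class `breakpoint_pair`.
#' @export
breakpoint_pair <- function(pos22, pos9, kind = c("forward", "reciprocal")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(pos22), is.numeric(pos9),
            length(pos22) == 1L, length(pos9) == 1L)
  structure(list(pos22 = as.numeric(pos22), pos9 = as.numeric(pos9),
                 kind = kind),
            class = "breakpoint_pair")
}

#' Per-chromosome deletion/duplication deltas of a reciprocal pair
#'
#' Quantifies the balance of a translocation from its forward
#' (BCR::ABL1-analog) and reciprocal (ABL1::BCR-analog) breakpoint
#' pairs. Deletion is positive, duplication negative; zero on both
#' chromosomes is a perfectly balanced translocation.
#'
#' @param fwd a [breakpoint_pair()] with `kind = "forward"`.
#' @param rec a [breakpoint_pair()] with `kind = "reciprocal"` from the
#'   same patient, or `NULL`/`NA` when no reciprocal fusion is known.
#' @param large_threshold size (bases) above which a
#'   deletion/duplication is flagged as large; 10 kbp by default.
#' @return an object of class `reciprocal_summary`: `delta22`, `delta9`
#'   (signed bases), `class22`, `class9`
#'   (`balanced`/`deletion`/`duplication`), `within_1bp` (both deltas
#'   within +/- 1), `within_100bp_22`, `within_100bp_9`,
#'   `large_del_22/9`, `large_dup_22/9`, `available`.
#' @export
#' @examples
#' fwd <- breakpoint_pair(1000, 5000, "forward")
#' rec <- breakpoint_pair(1001, 4999, "reciprocal")
#' reciprocal_deltas(fwd, rec)   # perfectly balanced
reciprocal_deltas <- function(fwd, rec, large_threshold = 10000) {
  stopifnot(inherits(fwd, "breakpoint_pair"))
  if (is.null(rec) || (!inherits(rec, "breakpoint_pair") && all(is.na(rec)))) {
    return(structure(list(available = FALSE), class = "reciprocal_summary"))
  }
  stopifnot(inherits(rec, "breakpoint_pair"))
  if (fwd$kind != "forward" || rec$kind != "reciprocal") {
    .stop_format("reciprocal_deltas needs a forward and a reciprocal pair, in that order")
  }
  delta22 <- rec$pos22 - fwd$pos22 - 1
  delta9 <- fwd$pos9 - rec$pos9 - 1
  classify <- function(d) {
    if (d == 0) "balanced" else if (d > 0) "deletion" else "duplication"
  }
  structure(
    list(available = TRUE,
         delta22 = delta22, delta9 = delta9,
         class22 = classify(delta22), class9 = classify(delta9),
         within_1bp = abs(delta22) <= 1 && abs(delta9) <= 1,
         within_100bp_22 = abs(delta22) <= 100,
         within_100bp_9 = abs(delta9) <= 100,
         large_del_22 = delta22 > large_threshold,
         large_del_9 = delta9 > large_threshold,
         large_dup_22 = delta22 < -large_threshold,
         large_dup_9 = delta9 < -large_threshold,
         large_threshold = large_threshold),
    class = "reciprocal_summary"
  )
}

#' @export
print.reciprocal_summary <- function(x, ...) {
  if (!x$available) {
    cat("<reciprocal_summary> reciprocal fusion unavailable\n")
    return(invisible(x))
  }
  cat(sprintf("<reciprocal_summary> delta22 = %s (%s), delta9 = %s (%s)%s\n",
              format(x$delta22, big.mark = ","), x$class22,
              format(x$delta9, big.mark = ","), x$class9,
              if (x$delta22 == 0 && x$delta9 == 0) " -- perfectly balanced" else ""))
  invisible(x)
}

#' Cohort-level reciprocal concordance report
#'
#' Computes the balance statistics of every patient carrying both a
#' forward and a reciprocal breakpoint pair: concordance windows
#' (perfect balance, +/- 1 bp on both genes, +/- 100 bp per gene),
#' large (> threshold) deletion/duplication counts per chromosome, and
#' extreme sizes. Percentages are reported together with their
#' denominator (`n_paired`).
#'
#' @param cohort a cohort `data.frame` with internal 0-based columns
#'   `pos22`, `pos9`, `pos22_rec`, `pos9_rec`.
#' @param large_threshold bases; see [reciprocal_deltas()].
#' @return a list of counts and percentages; see Details. Errors if no
#'   patient has both fusions.
#' @export
cohort_reciprocal_report <- function(cohort, large_threshold = 10000) {
  paired <- which(!is.na(cohort$pos22) & !is.na(cohort$pos9) &
                    !is.na(cohort$pos22_rec) & !is.na(cohort$pos9_rec))
  if (length(paired) == 0L) {
    .stop_format("no patient carries both the forward and the reciprocal fusion")
  }
  d22 <- cohort$pos22_rec[paired] - cohort$pos22[paired] - 1
  d9 <- cohort$pos9[paired] - cohort$pos9_rec[paired] - 1
  n <- length(paired)
  pct <- function(k) 100 * k / n
  n_within_1bp <- sum(abs(d22) <= 1 & abs(d9) <= 1)
  n_balanced <- sum(d22 == 0 & d9 == 0)
  n_100_22 <- sum(abs(d22) <= 100)
  n_100_9 <- sum(abs(d9) <= 100)
  list(
    n_paired = n,
    n_within_1bp_both = n_within_1bp,
    pct_within_1bp_both = pct(n_within_1bp),
    n_perfectly_balanced = n_balanced,
    pct_perfectly_balanced = pct(n_balanced),
    n_within_100bp_22 = n_100_22,
    pct_within_100bp_22 = pct(n_100_22),
    n_within_100bp_9 = n_100_9,
    pct_within_100bp_9 = pct(n_100_9),
    n_del_gt_thresh_22 = sum(d22 > large_threshold),
    n_del_gt_thresh_9 = sum(d9 > large_threshold),
    n_dup_gt_thresh_22 = sum(d22 < -large_threshold),
    n_dup_gt_thresh_9 = sum(d9 < -large_threshold),
    max_del_22 = if (any(d22 > 0)) max(d22) else 0,
    max_del_9 = if (any(d9 > 0)) max(d9) else 0,
    max_dup_22 = if (any(d22 < 0)) -min(d22) else 0,
    max_dup_9 = if (any(d9 < 0)) -min(d9) else 0,
    large_threshold = large_threshold
  )
}
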