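# Distribution analyses of breakpoint coordinates.

.dist_test_result <- function(method, statistic, p_value, n, params) {
  structure(
    list(method = method, statistic = as.numeric(statistic),
         p_value = as.numeric(p_value), n = n, params = params),
    class = "dist_test_result"
  )
}

#' @export
print.dist_test_result <- function(x, ...) {
  cat(sprintf("<dist_test_result> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(unlist(x$n), collapse = " + ")))
  invisible(x)
}

#' Chi-squared uniformity test of breakpoint positions within a region
#'
#' Bins positions into equal-width bins tiling the region and tests the
#' counts against the uniform expectation with Pearson's chi-squared
#' test (`df = bins - 1`). With `bin_width = "auto"` the largest bin
#' count with expected count >= 5 is used, capped at 100 bins -- a
#' standard validity rule for the chi-squared approximation.
#'
#' @param positions breakpoint coordinates (0-based), all inside
#'   `region`.
#' @param region a [genomic_region()].
#' @param bin_width bin width in bases, or `"auto"`.
#' @return a `dist_test_result` with method `"chisq_uniformity"`; its
#'   `params` carry the bin count, width and observed counts.
#' @export
uniformity_test <- function(positions, region, bin_width = "auto") {
  positions <- as.numeric(positions)
  n <- length(positions)
  if (n < 20L) .stop_format("uniformity_test needs n >= 20 positions (got %d)", n)
  if (!all(region_contains(region, positions))) {
    .stop_format("all positions must lie inside region %s", region$name)
  }
  width <- region_width(region)
  if (identical(bin_width, "auto")) {
    nbins <- max(2L, min(100L, floor(n / 5)))
  } else {
    if (!.is_count(bin_width, 1L)) .stop_format("bin_width must be a positive count or 'auto'")
    nbins <- max(2L, ceiling(width / bin_width))
    if (n / nbins < 1) {
      .stop_format(paste0("expected count below 1 per bin (%d bins for %d ",
                          "positions); widen bin_width or use 'auto'"),
                   nbins, n)
    }
  }
  breaks <- seq(region$start, region$end, length.out = nbins + 1L)
  counts <- tabulate(findInterval(positions, breaks,
                                  rightmost.closed = TRUE, all.inside = TRUE),
                     nbins)
  test <- suppressWarnings(stats::chisq.test(counts))
  .dist_test_result("chisq_uniformity", test$statistic, test$p.value, n,
                    list(bins = nbins, bin_width = width / nbins,
                         df = nbins - 1L, counts = counts))
}

#' Two-sample Kolmogorov-Smirnov comparison of breakpoint distributions
#'
#' Compares the empirical distributions of breakpoint coordinates
#' between two cohorts (e.g. CML vs ALL) with the two-sample KS test.
#' The p-value comes from the asymptotic Kolmogorov distribution with
#' effective sample size `nA * nB / (nA + nB)`; for small problems
#' (`nA * nB <= exact_limit`, no ties) the exact distribution is used.
#'
#' @param groupA,groupB coordinate vectors, both non-empty.
#' @param exact_limit use the exact small-sample p when
#'   `nA * nB <= exact_limit` (set to `0` to force asymptotic).
#' @return a `dist_test_result` with method `"ks_two_sample"`; `params`
#'   record whether the exact p was used and whether ties were present.
#' @export
ks_compare <- function(groupA, groupB, exact_limit = 10000) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  nA <- length(groupA); nB <- length(groupB)
  if (nA == 0L || nB == 0L) .stop_format("both groups must be non-empty")
  if (min(nA, nB) < 5L) {
    warning("a group has fewer than 5 positions; the KS p-value is unreliable",
            call. = FALSE)
  }
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  exact <- (as.numeric(nA) * nB <= exact_limit) && !ties
  test <- suppressWarnings(stats::ks.test(groupA, groupB, exact = exact))
  .dist_test_result("ks_two_sample", test$statistic, test$p.value,
                    list(nA = nA, nB = nB),
                    list(exact = exact, ties = ties,
                         effective_n = nA * nB / (nA + nB)))
}

#' Logistic-regression screen of a covariate against breakpoint position
#'
#' Fits a single-predictor logistic model with the binary covariate
#' class as outcome and the min-max-normalized position within the
#' region as predictor, and reports the likelihood-ratio test against
#' the intercept-only model. With one predictor this p-value is the
#' same whichever way the association is phrased (class given position
#' or position shift given class).
#'
#' @param positions breakpoint coordinates inside `region`.
#' @param region a [genomic_region()] used for min-max normalization.
#' @param covariate binary labels, same length as `positions` (factor,
#'   character or logical; exactly two classes present).
#' @return a `dist_test_result` with method `"logit_covariate"`;
#'   `params` include the slope on the normalized position and a
#'   `separation` flag (complete separation: the slope diverges, the
#'   LRT p is still returned).
#' @export
covariate_logit <- function(positions, region, covariate) {
  positions <- as.numeric(positions)
  if (length(positions) != length(covariate)) {
    .stop_format("positions and covariate must have the same length")
  }
  if (length(positions) < 30L) {
    .stop_format("covariate_logit needs n >= 30 (got %d)", length(positions))
  }
  if (!all(region_contains(region, positions))) {
    .stop_format("all positions must lie inside region %s", region$name)
  }
  y <- factor(covariate)
  if (nlevels(y) != 2L) .stop_format("covariate must have exactly two classes")
  x <- (positions - region$start) / region_width(region)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  lrt <- fit$null.deviance - fit$deviance
  p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  probs <- stats::fitted(fit)
  separation <- abs(stats::coef(fit)[["x"]]) > 15 &&
    (all(probs[y == levels(y)[2L]] > 1 - 1e-6) ||
       all(probs[y == levels(y)[2L]] < 1e-6) ||
       !fit$converged)
  .dist_test_result("logit_covariate", lrt, p,
                    list(n = length(positions),
                         per_class = as.list(table(y))),
                    list(slope = unname(stats::coef(fit)[["x"]]),
                         separation = separation))
}

#' Binned breakpoint density profile
#'
#' Counts breakpoints in equal-width bins tiling a region; the counts
#' always sum to the number of positions.
#'
#' @param positions coordinates inside `region` (may be empty).
#' @param region a [genomic_region()].
#' @param bin_width bin width in bases (the last bin absorbs any
#'   remainder so the bins tile the region exactly).
#' @return `data.frame` with `bin_start`, `bin_end` (0-based half-open)
#'   and `count`.
#' @export
density_profile <- function(positions, region, bin_width = 1000L) {
  positions <- as.numeric(positions)
  if (length(positions) && !all(region_contains(region, positions))) {
    .stop_format("all positions must lie inside region %s", region$name)
  }
  if (!.is_count(bin_width, 1L)) .stop_format("bin_width must be >= 1")
  width <- region_width(region)
  nbins <- max(1L, floor(width / bin_width))
  breaks <- region$start + c(seq(0, by = bin_width, length.out = nbins),
                             width)
  counts <- if (length(positions)) {
    tabulate(findInterval(positions, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins)
  } else rep(0L, nbins)
  data.frame(bin_start = breaks[seq_len(nbins)],
             bin_end = breaks[-1L],
             count = counts)
}
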