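# DNA motif scanning and breakpoint-proximity permutation testing.

.check_iupac <- function(pattern, what = "pattern") {
  bad <- regexpr(sprintf("[^%s]", paste(names(IUPAC_MAP), collapse = "")),
                 pattern)
  if (bad > 0) {
    .stop_format("invalid IUPAC code '%s' at position %d of %s '%s'",
                 substr(pattern, bad, bad), bad, what, pattern)
  }
  invisible(pattern)
}

#' Define a motif pattern
#'
#' Two kinds are supported: `"iupac"` -- a degenerate DNA pattern
#' matched with up to `max_mismatches` mismatches on both strands --
#' and `"rss"` -- a recombination signal sequence: heptamer
#' (consensus `CACAGTG`) and nonamer (consensus `ACAAAAACC`) separated
#' by a 12- or 23-base spacer, each element with its own mismatch
#' allowance.
#'
#' @param name motif label (used in reports and multiplicity
#'   correction).
#' @param kind `"iupac"` or `"rss"`.
#' @param pattern IUPAC string (iupac kind only).
#' @param max_mismatches mismatch allowance (iupac kind).
#' @param heptamer,nonamer RSS elements (rss kind).
#' @param spacer RSS spacer length, 12 or 23.
#' @param spacer_slack allowed deviation (bases) from the nominal
#'   spacer.
#' @param mm_heptamer,mm_nonamer per-element mismatch allowances (rss
#'   kind).
#' @return an object of class `motif_pattern`.
#' @export
#' @examples
#' motif_pattern("topoII", "iupac", "RNYNNCNNGYNGKTNYNY", max_mismatches = 2)
#' motif_pattern("RSS12", "rss", spacer = 12)
motif_pattern <- function(name, kind = c("iupac", "rss"), pattern = NULL,
                          max_mismatches = 0L,
                          heptamer = "CACAGTG", nonamer = "ACAAAAACC",
                          spacer = 12L, spacer_slack = 0L,
                          mm_heptamer = 0L, mm_nonamer = 0L) {
  kind <- match.arg(kind)
  if (kind == "iupac") {
    if (is.null(pattern) || !nzchar(pattern)) {
      .stop_format("iupac motif '%s' needs a non-empty pattern", name)
    }
    pattern <- toupper(pattern)
    .check_iupac(pattern)
  } else {
    if (!spacer %in% c(12L, 23L)) .stop_format("RSS spacer must be 12 or 23")
    heptamer <- toupper(heptamer); nonamer <- toupper(nonamer)
    .check_iupac(heptamer, "heptamer")
    .check_iupac(nonamer, "nonamer")
  }
  structure(
    list(name = name, kind = kind, pattern = pattern,
         max_mismatches = as.integer(max_mismatches),
         heptamer = heptamer, nonamer = nonamer,
         spacer = as.integer(spacer), spacer_slack = as.integer(spacer_slack),
         mm_heptamer = as.integer(mm_heptamer),
         mm_nonamer = as.integer(mm_nonamer)),
    class = "motif_pattern"
  )
}

#' Load motif definitions from a YAML config
#'
#' Reads a list of motif entries (fields as in [motif_pattern()]). The
#' package ships an illustrative catalog at
#' `system.file("extdata", "motifs.yaml", package = "breakfusion")`:
#' a small, clearly labeled subset of break-associated motifs
#' (topoisomerase II consensus, immunoglobulin switch-repeat pentamers,
#' RSS consensus), not any published exhaustive catalog.
#'
#' @param path YAML file.
#' @return a list of `motif_pattern` objects.
#' @export
load_motifs <- function(path) {
  if (!file.exists(path)) .stop_format("motif config not found: %s", path)
  entries <- yaml::read_yaml(path)
  if (!is.null(entries$motifs)) entries <- entries$motifs
  lapply(entries, function(e) {
    do.call(motif_pattern, e[intersect(names(e), names(formals(motif_pattern)))])
  })
}

# 0-based hit frame from a Biostrings match object
.hits_frame <- function(starts0, ends0, strand) {
  data.frame(start = as.numeric(starts0), end = as.numeric(ends0),
             strand = strand, stringsAsFactors = FALSE)
}

.match_starts0 <- function(pattern, subject_dna, max_mismatch) {
  m <- Biostrings::matchPattern(pattern, subject_dna,
                                max.mismatch = max_mismatch,
                                fixed = "subject")
  BiocGenerics::start(m) - 1L
}

#' Scan a sequence for a degenerate (IUPAC) motif
#'
#' Reports every position, on both strands, where the pattern matches
#' with at most `pattern$max_mismatches` mismatches; overlapping hits
#' are all reported. Minus-strand hits are matches of the reverse
#' complement, reported in plus-strand coordinates.
#'
#' @param seq subject sequence (character or `DNAString`).
#' @param pattern a `motif_pattern` of kind `"iupac"`.
#' @return `data.frame` with 0-based half-open `start`, `end` and
#'   `strand`.
#' @export
#' @examples
#' p <- motif_pattern("probe", "iupac", "ACGT")
#' scan_iupac("AACGTT", p)
scan_iupac <- function(seq, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (pattern$kind != "iupac") .stop_format("scan_iupac needs an iupac motif")
  seq <- .as_seq_string(seq)
  if (nchar(pattern$pattern) > nchar(seq)) {
    return(.hits_frame(numeric(0), numeric(0), character(0)))
  }
  subject <- Biostrings::DNAString(seq)
  w <- nchar(pattern$pattern)
  pat <- Biostrings::DNAString(pattern$pattern)
  plus <- .match_starts0(pat, subject, pattern$max_mismatches)
  minus <- .match_starts0(Biostrings::reverseComplement(pat), subject,
                          pattern$max_mismatches)
  rbind(.hits_frame(plus, plus + w, rep("+", length(plus))),
        .hits_frame(minus, minus + w, rep("-", length(minus))))
}

.scan_rss_plus <- function(subject, pattern) {
  h <- .match_starts0(Biostrings::DNAString(pattern$heptamer), subject,
                      pattern$mm_heptamer)
  if (length(h) == 0L) return(.hits_frame(numeric(0), numeric(0), character(0)))
  n <- .match_starts0(Biostrings::DNAString(pattern$nonamer), subject,
                      pattern$mm_nonamer)
  if (length(n) == 0L) return(.hits_frame(numeric(0), numeric(0), character(0)))
  hl <- nchar(pattern$heptamer); nl <- nchar(pattern$nonamer)
  rows <- list()
  for (hs in h) {
    gap <- n - (hs + hl)
    ok <- which(abs(gap - pattern$spacer) <= pattern$spacer_slack)
    for (j in ok) {
      rows[[length(rows) + 1L]] <- c(hs, n[j] + nl)
    }
  }
  if (length(rows) == 0L) return(.hits_frame(numeric(0), numeric(0), character(0)))
  mat <- do.call(rbind, rows)
  .hits_frame(mat[, 1L], mat[, 2L], rep("+", nrow(mat)))
}

#' Scan a sequence for recombination signal sequences (RSS)
#'
#' Finds heptamer/nonamer element pairs at the configured spacer
#' (12 or 23, with optional slack) and per-element mismatch allowances,
#' in either orientation. The RAG recombinase recognizes exactly this
#' architecture, which is why RSS-like sites are candidate break
#' initiators in lymphoid neoplasms.
#'
#' @param seq subject sequence.
#' @param pattern a `motif_pattern` of kind `"rss"`.
#' @return `data.frame` with 0-based half-open `start`, `end` (spanning
#'   heptamer through nonamer) and `strand`.
#' @export
scan_rss <- function(seq, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (pattern$kind != "rss") .stop_format("scan_rss needs an rss motif")
  seq <- .as_seq_string(seq)
  subject <- Biostrings::DNAString(seq)
  plus <- .scan_rss_plus(subject, pattern)
  rc <- Biostrings::reverseComplement(subject)
  on_rc <- .scan_rss_plus(rc, pattern)
  len <- nchar(seq)
  minus <- .hits_frame(len - on_rc$end, len - on_rc$start,
                       rep("-", nrow(on_rc)))
  rbind(plus, minus)
}

#' Scan with any motif kind
#'
#' Dispatches to [scan_iupac()] or [scan_rss()] by the motif's kind.
#'
#' @inheritParams scan_iupac
#' @return see [scan_iupac()].
#' @export
scan_motif <- function(seq, pattern) {
  if (pattern$kind == "rss") scan_rss(seq, pattern) else scan_iupac(seq, pattern)
}

#' Permutation test of breakpoint proximity to motif hits
#'
#' Tests whether breakpoints cluster within `window` bases of any motif
#' hit more often than expected. The observed statistic is the number
#' of breakpoints falling within +/- `window` of a (deduplicated) hit
#' interval; the null redraws the breakpoint positions `n_perm` times --
#' uniformly within the region (`null = "uniform"`), or from the binned
#' empirical breakpoint profile (`null = "density"`, which separates
#' motif attraction from regional non-uniformity) -- and
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`, so p is bounded
#' below by `1/(n_perm + 1)` and the test is deterministic for a fixed
#' seed.
#'
#' @param breakpoints coordinates (0-based) inside `region`.
#' @param hits motif hits: `data.frame` with 0-based half-open
#'   `start`/`end` (as from the scanners), possibly empty.
#' @param region a [genomic_region()].
#' @param window proximity window in bases (default +/- 10).
#' @param n_perm number of permutations (>= 1000 for a reportable p).
#' @param seed integer seed for the permutation draws.
#' @param null `"uniform"` or `"density"`.
#' @param density_bin bin width (bases) of the empirical profile used
#'   by the density-matched null.
#' @param motif label stored in the result.
#' @return an object of class `enrichment_result`: `observed`,
#'   `null_mean`, `null_sd`, `p_value`, `n_perm`, `n_breakpoints`,
#'   `flag` (`"ok"` or `"no_hits"`), `adjusted_p` (`NA` until set by
#'   [enrichment_scan()]).
#' @export
proximity_enrichment <- function(breakpoints, hits, region, window = 10L,
                                 n_perm = 10000L, seed = 1L,
                                 null = c("uniform", "density"),
                                 density_bin = 1000L, motif = "motif") {
  null <- match.arg(null)
  breakpoints <- as.numeric(breakpoints)
  nb <- length(breakpoints)
  if (nb == 0L) .stop_format("no breakpoints supplied")
  if (!all(region_contains(region, breakpoints))) {
    .stop_format("all breakpoints must lie inside region %s", region$name)
  }
  if (n_perm < 1000L) {
    warning("n_perm below 1000; the permutation p-value is coarse", call. = FALSE)
  }
  res <- function(observed, null_mean, null_sd, p, flag) {
    structure(list(motif = motif, window = as.integer(window),
                   observed = observed, null_mean = null_mean,
                   null_sd = null_sd, p_value = p,
                   n_perm = as.integer(n_perm), n_breakpoints = nb,
                   null = null, flag = flag, adjusted_p = NA_real_),
              class = "enrichment_result")
  }
  if (is.null(hits) || nrow(hits) == 0L) {
    return(res(0L, 0, 0, 1, "no_hits"))
  }
  hits <- unique(hits[, c("start", "end")])
  width <- region_width(region)
  mask <- logical(width)
  lo <- pmax(floor(hits$start) - window, region$start)
  hi <- pmin(ceiling(hits$end) - 1 + window, region$end - 1)
  for (i in seq_len(nrow(hits))) {
    if (lo[i] <= hi[i]) {
      mask[(lo[i] - region$start + 1):(hi[i] - region$start + 1)] <- TRUE
    }
  }
  observed <- sum(mask[breakpoints - region$start + 1])
  set.seed(split_seed(seed, 404L))
  if (null == "uniform") {
    draws <- sample.int(width, nb * n_perm, replace = TRUE)
  } else {
    prof <- density_profile(breakpoints, region, density_bin)
    bins <- sample.int(nrow(prof), nb * n_perm, replace = TRUE,
                       prob = prof$count / nb)
    lo_b <- prof$bin_start[bins] - region$start + 1
    hi_b <- prof$bin_end[bins] - region$start
    draws <- floor(stats::runif(nb * n_perm, lo_b, hi_b + 1))
  }
  null_counts <- colSums(matrix(mask[draws], nrow = nb))
  p <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  res(observed, mean(null_counts), stats::sd(null_counts), p, "ok")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s: observed %d/%d within +/-%d bp (null %.2f +/- %.2f), p = %.4g%s\n",
    x$motif, x$observed, x$n_breakpoints, x$window, x$null_mean, x$null_sd,
    x$p_value, if (x$flag != "ok") sprintf(" [%s]", x$flag) else ""))
  invisible(x)
}

#' Proximity enrichment across a motif catalog
#'
#' Scans the sequence for every motif, runs [proximity_enrichment()]
#' per motif, and applies Benjamini-Hochberg correction across the
#' catalog.
#'
#' @param breakpoints coordinates inside `region`.
#' @param motifs list of `motif_pattern` objects (see [load_motifs()]).
#' @param seq the sequence of the chromosome carrying `region`.
#' @param region a [genomic_region()].
#' @inheritParams proximity_enrichment
#' @return `data.frame` with one row per motif: `motif`, `n_hits`,
#'   `observed`, `null_mean`, `null_sd`, `p_value`, `adjusted_p`,
#'   `flag`.
#' @export
enrichment_scan <- function(breakpoints, motifs, seq, region, window = 10L,
                            n_perm = 10000L, seed = 1L,
                            null = c("uniform", "density")) {
  null <- match.arg(null)
  seq <- .as_seq_string(seq)
  rows <- lapply(seq_along(motifs), function(i) {
    m <- motifs[[i]]
    hits <- scan_motif(seq, m)
    er <- proximity_enrichment(breakpoints, hits, region, window = window,
                               n_perm = n_perm,
                               seed = split_seed(seed, 500L + i),
                               null = null, motif = m$name)
    data.frame(motif = m$name, n_hits = nrow(unique(hits[, c("start", "end")])),
               observed = er$observed, null_mean = er$null_mean,
               null_sd = er$null_sd, p_value = er$p_value,
               flag = er$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out
}
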