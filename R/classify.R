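# Junction primary-structure classification.
#
# A fusion sequence F is decomposed against its two partner references by
#   p = length of the maximal contiguous prefix of F matching partner A
#       from its aligned start, and
#   s = length of the maximal contiguous suffix of F matching partner B
#       up to its aligned end.
# Then exactly one of three cases holds:
#   p + s == |F|  -> blunt join (no shared, no extra bases)
#   p + s  > |F|  -> microhomology of h = p + s - |F| shared bases; the
#                    crossover is ambiguous over h + 1 placements and is
#                    canonicalized to the leftmost (5'-most on partner A)
#   p + s  < |F|  -> untemplated insertion of F[p+1 .. |F|-s]
# A tie between microhomology and insertion is impossible: an insertion
# requires p + s < |F| while microhomology requires p + s > |F|.

.unanchored <- function(fmt, ...) {
  stop(structure(
    class = c("unanchored_junction", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

# candidate 0-based start positions of `pat` within `subject`
.exact_starts <- function(pat, subject_dna) {
  m <- Biostrings::matchPattern(pat, subject_dna)
  BiocGenerics::start(m) - 1L
}

# Align the prefix of `fusion` to refA: returns list(start0, p) for the
# best candidate (max contiguous prefix match; anchor proximity breaks
# ties; then leftmost).
.align_prefix <- function(fusion_raw, refA_raw, refA_dna, k, anchorA,
                          anchor_window) {
  L <- length(fusion_raw)
  if (L < k) .unanchored("fusion sequence shorter than the minimum anchor (%d)", k)
  pat <- rawToChar(fusion_raw[seq_len(k)])
  starts <- .exact_starts(pat, refA_dna)
  if (length(starts) == 0L) {
    .unanchored("fusion prefix has no %d-base anchor in partner A", k)
  }
  p <- vapply(starts, function(s0) {
    span <- min(L, length(refA_raw) - s0)
    .match_prefix_len(fusion_raw[seq_len(span)],
                      refA_raw[(s0 + 1):(s0 + span)])
  }, integer(1L))
  keep <- seq_along(starts)
  if (!is.null(anchorA) && !is.na(anchorA)) {
    cross <- starts + p - 1          # implied last matched base on A
    within <- abs(cross - anchorA) <= anchor_window
    if (any(within)) keep <- which(within)
  }
  best_p <- max(p[keep])
  cand <- keep[p[keep] == best_p]
  if (length(cand) > 1L && !is.null(anchorA) && !is.na(anchorA)) {
    cross <- starts[cand] + best_p - 1
    cand <- cand[order(abs(cross - anchorA), starts[cand])]
  }
  list(start0 = starts[cand[1L]], p = best_p)
}

# Align the suffix of `fusion` to refB: returns list(end0, s) where end0
# is the 0-based position just after the last fusion base in refB.
.align_suffix <- function(fusion_raw, refB_raw, refB_dna, k, anchorB,
                          anchor_window) {
  L <- length(fusion_raw)
  if (L < k) .unanchored("fusion sequence shorter than the minimum anchor (%d)", k)
  pat <- rawToChar(fusion_raw[(L - k + 1):L])
  starts <- .exact_starts(pat, refB_dna)
  if (length(starts) == 0L) {
    .unanchored("fusion suffix has no %d-base anchor in partner B", k)
  }
  ends <- starts + k                # 0-based exclusive alignment end
  frev <- rev(fusion_raw)
  s <- vapply(ends, function(e0) {
    span <- min(L, e0)
    .match_prefix_len(frev[seq_len(span)],
                      rev(refB_raw[(e0 - span + 1):e0]))
  }, integer(1L))
  keep <- seq_along(ends)
  if (!is.null(anchorB) && !is.na(anchorB)) {
    cross <- ends - s               # implied first matched base on B
    within <- abs(cross - anchorB) <= anchor_window
    if (any(within)) keep <- which(within)
  }
  best_s <- max(s[keep])
  cand <- keep[s[keep] == best_s]
  if (length(cand) > 1L && !is.null(anchorB) && !is.na(anchorB)) {
    cross <- ends[cand] - best_s
    cand <- cand[order(abs(cross - anchorB), ends[cand])]
  }
  list(end0 = ends[cand[1L]], s = best_s)
}

#' Classify the primary structure of a fusion junction
#'
#' Decomposes a junction-spanning fusion sequence against its two partner
#' references into canonical breakpoints plus a mechanism call:
#' `microhomology` (shared bases at the crossover), `blunt` (clean join)
#' or `insertion` (untemplated bases matching neither flank). These are
#' the junction signatures expected from non-homologous end joining.
#'
#' The fusion prefix is anchored in `refA` and the suffix in `refB` by an
#' exact seed of `min_anchor` bases; `anchorA`/`anchorB` (approximate
#' crossover coordinates, 0-based) disambiguate repeated seeds when
#' given. Within a microhomology the crossover is placed at the leftmost
#' (5'-most on partner A) equivalent position; see
#' [breakpoint_coordinates]. IUPAC ambiguity codes in the references are
#' treated as mismatches, which keeps homology calls conservative.
#'
#' @param fusion_seq the junction-spanning nucleotide string.
#' @param refA,refB partner reference sequences (character or
#'   `DNAString`); the fusion runs A -> B on the plus strand.
#' @param anchorA,anchorB optional approximate crossover coordinates
#'   (0-based) on each partner, used to resolve ambiguous seed matches.
#' @param min_anchor minimum contiguous match (bases) required on each
#'   side to call the junction; below it the junction is rejected as
#'   unanchored (an error of class `unanchored_junction`).
#' @param anchor_window maximum distance (bases) between an implied
#'   crossover and a supplied anchor for a candidate alignment to count.
#' @return an object of class `junction_call`: a list with `mechanism`,
#'   `mh_len`, `ins_seq`, `canonical_posA` (0-based last retained base of
#'   A), `canonical_posB` (0-based first retained base of B),
#'   `ambiguity_window` (= `mh_len + 1`), and the raw decomposition
#'   (`p`, `s`, `startA`, `endB`, `fusion_len`).
#' @export
#' @examples
#' refA <- paste0(strrep("ACGGT", 10), "AAAA")
#' refB <- paste0("TTTT", strrep("CTGAC", 10))
#' fus <- paste0(substr(refA, 31, 54), substr(refB, 1, 24))
#' classify_junction(fus, refA, refB)$mechanism  # "blunt"
classify_junction <- function(fusion_seq, refA, refB,
                              anchorA = NULL, anchorB = NULL,
                              min_anchor = 12L, anchor_window = 5000L) {
  fusion_seq <- .as_seq_string(fusion_seq, "fusion_seq")
  refA <- .as_seq_string(refA, "refA")
  refB <- .as_seq_string(refB, "refB")
  if (!.is_count(min_anchor, 1L)) .stop_format("min_anchor must be >= 1")
  fusion_raw <- .seq_raw(fusion_seq)
  L <- length(fusion_raw)
  refA_raw <- .seq_raw(refA)
  refB_raw <- .seq_raw(refB)
  refA_dna <- Biostrings::BString(refA)
  refB_dna <- Biostrings::BString(refB)

  pre <- .align_prefix(fusion_raw, refA_raw, refA_dna, min_anchor,
                       anchorA, anchor_window)
  suf <- .align_suffix(fusion_raw, refB_raw, refB_dna, min_anchor,
                       anchorB, anchor_window)
  p <- pre$p
  s <- suf$s
  if (p < min_anchor) .unanchored("prefix match (%d) below minimum anchor (%d)", p, min_anchor)
  if (s < min_anchor) .unanchored("suffix match (%d) below minimum anchor (%d)", s, min_anchor)

  if (p + s == L) {
    mechanism <- "blunt"; h <- 0L; ins <- ""
    pA <- p; sB <- s
  } else if (p + s > L) {
    mechanism <- "microhomology"; h <- p + s - L; ins <- ""
    pA <- L - s; sB <- s            # leftmost: A contributes as little as possible
  } else {
    mechanism <- "insertion"; h <- 0L
    ins <- substr(fusion_seq, p + 1L, L - s)
    pA <- p; sB <- s
  }
  structure(
    list(mechanism = mechanism,
         mh_len = as.integer(h),
         ins_seq = ins,
         canonical_posA = pre$start0 + pA - 1L,
         canonical_posB = suf$end0 - sB,
         ambiguity_window = as.integer(h) + 1L,
         p = as.integer(p), s = as.integer(s),
         startA = pre$start0, endB = suf$end0,
         fusion_len = as.integer(L)),
    class = "junction_call"
  )
}

#' @export
print.junction_call <- function(x, ...) {
  detail <- switch(x$mechanism,
    microhomology = sprintf("h = %d (ambiguity window %d)",
                            x$mh_len, x$ambiguity_window),
    insertion = sprintf("ins = %s (%d bp)", x$ins_seq, nchar(x$ins_seq)),
    "clean join")
  cat(sprintf("<junction_call> %s; %s; canonical posA = %s, posB = %s\n",
              x$mechanism, detail,
              format(x$canonical_posA, big.mark = ","),
              format(x$canonical_posB, big.mark = ",")))
  invisible(x)
}

#' Classify every junction in a cohort
#'
#' Runs [classify_junction()] on each record carrying a junction
#' sequence, using its stored breakpoint coordinates as alignment
#' anchors, and summarizes the mechanism mixture.
#'
#' @param cohort a cohort `data.frame` as returned by
#'   [read_cohort_table()] or [simulate_cohort()], with columns
#'   `patient_id`, `pos22`, `pos9` and `junction_seq`.
#' @param refA,refB the chr22-analog and chr9-analog reference sequences.
#' @param min_anchor,anchor_window passed to [classify_junction()].
#' @return a list with `calls` (per-junction `data.frame`), `fractions`
#'   (mechanism proportions over classifiable records, summing to 1),
#'   `mh_summary` / `ins_summary` (median and range of microhomology and
#'   insertion lengths, computed only within the matching mechanism
#'   class), `n_classifiable`, and `unclassifiable` (patient ids with the
#'   rejection reason -- e.g. complex events whose flanks cannot be
#'   anchored).
#' @export
classify_cohort <- function(cohort, refA, refB, min_anchor = 12L,
                            anchor_window = 5000L) {
  has_seq <- !is.na(cohort$junction_seq) & nzchar(cohort$junction_seq)
  if (!any(has_seq)) .stop_format("no records carry a junction sequence")
  idx <- which(has_seq)
  refA <- .as_seq_string(refA, "refA")
  refB <- .as_seq_string(refB, "refB")
  rows <- vector("list", length(idx))
  unclass_id <- character(0)
  unclass_reason <- character(0)
  for (j in seq_along(idx)) {
    i <- idx[j]
    call <- tryCatch(
      classify_junction(cohort$junction_seq[i], refA, refB,
                        anchorA = cohort$pos22[i], anchorB = cohort$pos9[i],
                        min_anchor = min_anchor,
                        anchor_window = anchor_window),
      unanchored_junction = function(e) e
    )
    if (inherits(call, "junction_call")) {
      rows[[j]] <- data.frame(
        patient_id = cohort$patient_id[i],
        mechanism = call$mechanism,
        mh_len = call$mh_len,
        ins_len = nchar(call$ins_seq),
        ins_seq = call$ins_seq,
        posA = call$canonical_posA,
        posB = call$canonical_posB,
        ambiguity_window = call$ambiguity_window,
        stringsAsFactors = FALSE
      )
    } else {
      unclass_id <- c(unclass_id, cohort$patient_id[i])
      unclass_reason <- c(unclass_reason, conditionMessage(call))
    }
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(calls) || nrow(calls) == 0L) {
    .stop_format("zero classifiable junctions (%d rejected as unanchored)",
                 length(unclass_id))
  }
  mechs <- c("microhomology", "blunt", "insertion")
  fractions <- as.numeric(table(factor(calls$mechanism, levels = mechs))) /
    nrow(calls)
  names(fractions) <- mechs
  summarize_len <- function(x) {
    if (length(x) == 0L) {
      list(n = 0L, median = NA_real_, min = NA_real_, max = NA_real_)
    } else {
      list(n = length(x), median = stats::median(x),
           min = min(x), max = max(x))
    }
  }
  list(
    calls = calls,
    fractions = fractions,
    mh_summary = summarize_len(calls$mh_len[calls$mechanism == "microhomology"]),
    ins_summary = summarize_len(calls$ins_len[calls$mechanism == "insertion"]),
    n_classifiable = nrow(calls),
    unclassifiable = data.frame(patient_id = unclass_id,
                                reason = unclass_reason,
                                stringsAsFactors = FALSE)
  )
}
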