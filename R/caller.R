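# Split-read fusion breakpoint calling.
#
# Desk-scale seed-and-extend caller for junction-spanning reads against
# two small partner references: exact k-mer seeds anchor a read prefix
# in partner A and a read suffix in partner B; the best split
# (optionally with an untemplated insert between the two sides) is the
# one minimizing mismatches, then insert length; per-read votes are
# clustered within +/- 3 bases and a per-column majority consensus
# junction is rebuilt and classified. Everything is deterministic.

# 2-bit encoding lookup: byte value -> base code (A0 C1 G2 T3, else NA)
.base_code_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[as.integer(charToRaw("A")) + 1L] <- 0L
  lut[as.integer(charToRaw("C")) + 1L] <- 1L
  lut[as.integer(charToRaw("G")) + 1L] <- 2L
  lut[as.integer(charToRaw("T")) + 1L] <- 3L
  lut
})

.base_codes <- function(raw) .base_code_lut[as.integer(raw) + 1L]

# codes of all k-mers of a code vector (double-precision exact; NA where
# the window contains a non-ACGT base)
.kmer_codes <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0))
  out <- numeric(n)
  for (j in seq_len(k)) {
    out <- out + codes[j:(j + n - 1L)] * 4^(k - j)
  }
  out
}

# sorted k-mer index of a reference string
.kmer_index <- function(ref_raw, k) {
  codes <- .kmer_codes(.base_codes(ref_raw), k)
  keep <- which(!is.na(codes))
  ord <- keep[order(codes[keep])]
  sorted <- codes[ord]
  n <- length(sorted)
  multi <- logical(n)
  if (n > 1L) {
    eq_next <- sorted[-n] == sorted[-1L]
    multi <- c(eq_next, FALSE) | c(FALSE, eq_next)
  }
  list(sorted = sorted, pos0 = ord - 1L, multi = multi, k = k,
       len = length(ref_raw))
}

# vectorized lookup: for each query code return the 0-based k-mer start,
# NA if absent, -1 if the k-mer occurs more than once
.kmer_lookup <- function(index, queries) {
  out <- rep(NA_real_, length(queries))
  ok <- !is.na(queries)
  if (!any(ok)) return(out)
  idx <- findInterval(queries[ok], index$sorted)
  hit <- idx >= 1L & index$sorted[pmax(idx, 1L)] == queries[ok]
  res <- rep(NA_real_, sum(ok))
  res[hit] <- ifelse(index$multi[idx[hit]], -1, index$pos0[idx[hit]])
  out[ok] <- res
  out
}

# slide a zero-insert crossover to its leftmost equivalent placement
.canonical_left <- function(refA_raw, refB_raw, posA0, posB0) {
  while (posA0 >= 0L && posB0 >= 1L &&
         refA_raw[posA0 + 1L] == refB_raw[posB0]) {
    posA0 <- posA0 - 1L
    posB0 <- posB0 - 1L
  }
  c(posA0, posB0)
}

# best split of one read; returns NULL with a reason attribute on discard
.split_read <- function(read_raw, read_codes, idxA, idxB, refA_raw, refB_raw,
                        min_anchor, max_mismatch_rate, max_ins) {
  L <- length(read_raw)
  k <- idxA$k
  nq <- length(read_codes)
  if (nq < 1L || L < 2L * min_anchor) return(structure(list(), reason = "too_short"))
  hitsA <- .kmer_lookup(idxA, read_codes)
  hitsB <- .kmer_lookup(idxB, read_codes)

  jA <- which(!is.na(hitsA))[1L]           # first anchored prefix seed
  jB_all <- which(!is.na(hitsB))
  jB <- if (length(jB_all)) jB_all[length(jB_all)] else NA_integer_
  if (is.na(jA) || is.na(jB)) {
    # diagnose: could the read fit the swapped orientation?
    jA2 <- which(!is.na(hitsB))[1L]
    jB2_all <- which(!is.na(hitsA))
    jB2 <- if (length(jB2_all)) jB2_all[length(jB2_all)] else NA_integer_
    reason <- if (!is.na(jA2) && !is.na(jB2)) "swapped_orientation" else "no_anchor"
    return(structure(list(), reason = reason))
  }
  if (jB < jA) {
    # suffix anchors upstream of the prefix anchor: the read runs B -> A
    return(structure(list(), reason = "swapped_orientation"))
  }
  if (hitsA[jA] < 0 || hitsB[jB] < 0) {
    return(structure(list(), reason = "ambiguous_seed"))
  }
  startA0 <- hitsA[jA] - (jA - 1L)          # 0-based read start on A
  endB0 <- hitsB[jB] + L - jB + 1L          # 0-based exclusive read end on B
  if (startA0 < 0 || endB0 > idxB$len) {
    return(structure(list(), reason = "no_anchor"))
  }

  # per-position mismatch vectors against each reference (pad = mismatch)
  vecA <- rep(TRUE, L)
  spanA <- min(L, idxA$len - startA0)
  if (spanA > 0L) {
    vecA[seq_len(spanA)] <-
      read_raw[seq_len(spanA)] != refA_raw[(startA0 + 1L):(startA0 + spanA)]
  }
  vecB <- rep(TRUE, L)
  spanB <- min(L, endB0)
  if (spanB > 0L) {
    vecB[(L - spanB + 1L):L] <-
      read_raw[(L - spanB + 1L):L] != refB_raw[(endB0 - spanB + 1L):endB0]
  }
  cumA <- cumsum(vecA)                      # mismatches in read[1..t]
  sufB <- rev(cumsum(rev(vecB)))            # mismatches in read[t..L]
  sufB_pad <- c(sufB, 0)

  p <- .match_prefix_len(read_raw, refA_raw[(startA0 + 1L):(startA0 + spanA)])
  s_run <- which(rev(vecB))[1L]
  s <- if (is.na(s_run)) L else s_run - 1L
  if (p < min_anchor || s < min_anchor) {
    return(structure(list(), reason = "short_anchor"))
  }

  if (p + s >= L) {                         # exact blunt / microhomology
    t1 <- L - s
    best <- list(mism = 0L, d = 0L, t1 = t1)
  } else if (L - p - s <= max_ins) {        # exact untemplated insertion:
    # the zero-mismatch split with the minimal insert is unique (t1 = p)
    # and beats every competing explanation under the (mismatches,
    # insert length) ordering, which keeps clean-read calls exact
    best <- list(mism = 0L, d = L - p - s, t1 = p)
  } else {
    # mismatch-tolerant search, minimizing (mismatches, insert length),
    # leftmost split on ties; individual error-bearing reads may vote
    # for a slightly shifted split, which majority voting absorbs
    best <- NULL
    dmax <- min(max_ins, L - 2L * min_anchor)
    for (d in 0:dmax) {
      t1s <- min_anchor:(L - min_anchor - d)
      costs <- cumA[t1s] + sufB_pad[t1s + d + 1L]
      m <- min(costs)
      if (is.null(best) || m < best$mism) {
        best <- list(mism = m, d = d, t1 = t1s[which.min(costs)])
      }
      if (best$mism == 0L) break
    }
    if (best$mism / L > max_mismatch_rate) {
      return(structure(list(), reason = "high_mismatch"))
    }
  }
  t1 <- best$t1; d <- best$d
  posA0 <- startA0 + t1 - 1L                # 0-based last A base
  posB0 <- endB0 - L + t1 + d               # 0-based first B base
  ins <- if (d > 0L) rawToChar(read_raw[(t1 + 1L):(t1 + d)]) else ""
  if (d == 0L) {
    can <- .canonical_left(refA_raw, refB_raw, posA0, posB0)
    posA0 <- can[1L]; posB0 <- can[2L]
  }
  list(posA = posA0, posB = posB0, d = d, ins = ins, mism = best$mism)
}

#' Call fusion breakpoints from junction-spanning reads
#'
#' Seed-and-extend split-read caller for a translocation with two small
#' partner references (the scale of captured breakpoint cluster
#' regions). Each read is anchored by exact `min_anchor`-mer seeds --
#' prefix in `refA`, suffix in `refB` -- and decomposed at the split
#' minimizing (mismatches, untemplated-insert length). Reads mapping in
#' the opposite orientation (prefix in B, suffix in A: reciprocal-fusion
#' reads) are skipped here and recovered by re-running with `refA` and
#' `refB` swapped. Per-read votes are leftmost-canonicalized, clustered
#' within `cluster_window` bases on both coordinates, turned into a
#' majority consensus junction, and classified with
#' [classify_junction()].
#'
#' @param reads named character vector of read sequences (see
#'   [read_junction_reads()]) or a `DNAStringSet`.
#' @param refA,refB partner references (character or `DNAString`); calls
#'   are reported as `posA` = last retained base of `refA` (0-based) and
#'   `posB` = first retained base of `refB`.
#' @param min_anchor exact seed length and minimum aligned bases
#'   required on each side of a split.
#' @param min_support minimum reads supporting a call.
#' @param max_mismatch_rate per-read cap on the mismatch fraction.
#' @param max_ins largest untemplated insert considered.
#' @param cluster_window votes within this many bases (both coordinates)
#'   are merged into one candidate; absorbs canonicalization jitter from
#'   sequencing errors.
#' @param consensus_flank reference flank (bases) used to rebuild the
#'   consensus junction sequence.
#' @return a `data.frame` of class `fusion_calls`, one row per called
#'   junction: `posA`, `posB`, `mechanism`, `mh_len`, `ins_seq`,
#'   `ambiguity_window`, `support`, `junction_consensus`. The
#'   `"discarded"` attribute tabulates per-read rejection reasons. An
#'   empty frame (zero calls) is a valid result, not an error.
#' @export
call_fusion <- function(reads, refA, refB, min_anchor = 12L,
                        min_support = 2L, max_mismatch_rate = 0.05,
                        max_ins = 60L, cluster_window = 3L,
                        consensus_flank = 100L) {
  if (inherits(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  refA <- .as_seq_string(refA, "refA")
  refB <- .as_seq_string(refB, "refB")
  refA_raw <- .seq_raw(refA)
  refB_raw <- .seq_raw(refB)
  k <- as.integer(min_anchor)
  idxA <- .kmer_index(refA_raw, k)
  idxB <- .kmer_index(refB_raw, k)

  empty <- data.frame(posA = numeric(0), posB = numeric(0),
                      mechanism = character(0), mh_len = integer(0),
                      ins_seq = character(0), ambiguity_window = integer(0),
                      support = integer(0),
                      junction_consensus = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("fusion_calls", class(empty))

  if (length(reads) == 0L) {
    attr(empty, "discarded") <- table(character(0))
    return(empty)
  }

  cand <- vector("list", length(reads))
  reasons <- character(length(reads))
  for (i in seq_along(reads)) {
    rr <- .seq_raw(toupper(reads[[i]]))
    rc <- .kmer_codes(.base_codes(rr), k)
    res <- .split_read(rr, rc, idxA, idxB, refA_raw, refB_raw,
                       k, max_mismatch_rate, max_ins)
    if (length(res)) {
      cand[[i]] <- res
    } else {
      reasons[i] <- attr(res, "reason")
    }
  }
  keep <- !vapply(cand, is.null, logical(1L))
  discarded <- table(reasons[reasons != ""])
  if (!any(keep)) {
    attr(empty, "discarded") <- discarded
    return(empty)
  }
  votes <- data.frame(
    posA = vapply(cand[keep], `[[`, numeric(1L), "posA"),
    posB = vapply(cand[keep], `[[`, numeric(1L), "posB"),
    d = vapply(cand[keep], function(x) as.numeric(x$d), numeric(1L)),
    ins = vapply(cand[keep], `[[`, character(1L), "ins"),
    stringsAsFactors = FALSE
  )

  # greedy clustering of vote pairs within +/- cluster_window
  pair_key <- paste(votes$posA, votes$posB)
  tab <- sort(table(pair_key), decreasing = TRUE)
  uniq <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  upairs <- data.frame(posA = as.numeric(uniq[, 1L]),
                       posB = as.numeric(uniq[, 2L]),
                       n = as.integer(tab), assigned = FALSE)
  calls <- list()
  for (u in seq_len(nrow(upairs))) {
    if (upairs$assigned[u]) next
    members <- which(!upairs$assigned &
                       abs(upairs$posA - upairs$posA[u]) <= cluster_window &
                       abs(upairs$posB - upairs$posB[u]) <= cluster_window)
    upairs$assigned[members] <- TRUE
    rows <- which(pair_key %in% paste(upairs$posA[members],
                                      upairs$posB[members]))
    support <- length(rows)
    if (support < min_support) next
    # majority consensus: modal insert length, then per-column majority
    # over the inserts of that length, anchored at the modal vote pair
    d_mode <- as.integer(names(sort(table(votes$d[rows]),
                                    decreasing = TRUE))[1L])
    rows_d <- rows[votes$d[rows] == d_mode]
    key_mode <- names(sort(table(pair_key[rows_d]), decreasing = TRUE))[1L]
    rep_row <- rows_d[pair_key[rows_d] == key_mode][1L]
    posA <- votes$posA[rep_row]; posB <- votes$posB[rep_row]
    ins <- ""
    if (d_mode > 0L) {
      mat <- do.call(rbind, strsplit(votes$ins[rows_d], "", fixed = TRUE))
      ins <- paste(apply(mat, 2L, function(col) {
        names(sort(table(col), decreasing = TRUE))[1L]
      }), collapse = "")
    }
    fl_a <- min(consensus_flank, posA + 1L)
    fl_b <- min(consensus_flank, nchar(refB) - posB)
    consensus <- paste0(substr(refA, posA - fl_a + 2L, posA + 1L), ins,
                        substr(refB, posB + 1L, posB + fl_b))
    jc <- tryCatch(
      classify_junction(consensus, refA, refB,
                        anchorA = posA, anchorB = posB,
                        min_anchor = min_anchor),
      unanchored_junction = function(e) NULL
    )
    if (is.null(jc)) next
    calls[[length(calls) + 1L]] <- data.frame(
      posA = jc$canonical_posA, posB = jc$canonical_posB,
      mechanism = jc$mechanism, mh_len = jc$mh_len,
      ins_seq = jc$ins_seq, ambiguity_window = jc$ambiguity_window,
      support = support, junction_consensus = consensus,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty
  out <- out[order(out$posA, out$posB), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fusion_calls", class(out))
  attr(out, "discarded") <- discarded
  out
}
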