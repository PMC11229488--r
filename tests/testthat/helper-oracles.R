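# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own decomposition/arithmetic
# code paths: the oracle enumerates explanations by brute force.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force junction decomposition oracle.
#
# Frame: fusion[1..L] is aligned so fusion[1] sits at 0-based `startA`
# in refA and fusion[L] sits at 0-based `endB - 1` in refB. Enumerates
# every explanation (t1, t2) with 0 <= t1 <= t2 <= L such that
# fusion[1..t1] matches refA and fusion[t2+1..L] matches refB at those
# alignments, picks the minimal insertion length t2 - t1, and within it
# the leftmost crossover. Returns NULL when no explanation exists.
oracle_decompose <- function(fusion, refA, refB, startA, endB) {
  L <- nchar(fusion)
  fch <- strsplit(fusion, "")[[1]]
  ach <- strsplit(substr(refA, startA + 1, startA + L), "")[[1]]
  bseg <- substr(refB, endB - L + 1, endB)
  bch <- strsplit(bseg, "")[[1]]
  # pad so indexing is safe when the alignment runs off a reference
  length(ach) <- L
  bch <- c(rep(NA_character_, L - length(bch)), bch)
  eqA <- !is.na(ach) & fch == ach
  eqB <- !is.na(bch) & fch == bch
  valid_t1 <- c(0, which(cumsum(!eqA) == 0))          # prefix explanations
  valid_t2 <- c(L - which(cumsum(rev(!eqB)) == 0), L) # suffix explanations
  best <- NULL
  for (t1 in valid_t1) {
    for (t2 in valid_t2) {
      if (t2 < t1) next
      d <- t2 - t1
      if (is.null(best) || d < best$d || (d == best$d && t1 < best$t1)) {
        best <- list(t1 = t1, t2 = t2, d = d)
      }
    }
  }
  if (is.null(best)) return(NULL)
  # equivalent zero-insertion placements = the microhomology window
  n_equiv <- if (best$d == 0) {
    length(intersect(valid_t1, valid_t2))
  } else 1L
  mech <- if (best$d > 0) "insertion" else if (n_equiv > 1L) "microhomology" else "blunt"
  list(
    mechanism = mech,
    mh_len = if (best$d == 0) n_equiv - 1L else 0L,
    ins_seq = if (best$d > 0) substr(fusion, best$t1 + 1, best$t2) else "",
    posA = startA + best$t1 - 1,
    posB = endB - (L - best$t2),
    n_explanations_min_d = n_equiv
  )
}

# Set-arithmetic oracle for reciprocal balance: explicitly lists the
# bases retained on each derivative and counts orphaned (deleted) and
# doubled (duplicated) bases. Coordinates 0-based on a chromosome of
# `len` bases.
oracle_deltas <- function(p22f, p9f, p22r, p9r, len) {
  chr22_fwd <- 0:p22f                 # chr22 bases on der(22)
  chr22_rec <- p22r:(len - 1)         # chr22 bases on der(9)
  chr9_fwd <- p9f:(len - 1)           # chr9 bases on der(22)
  chr9_rec <- 0:p9r                   # chr9 bases on der(9)
  count22_lost <- length(setdiff(0:(len - 1), union(chr22_fwd, chr22_rec)))
  count22_dup <- length(intersect(chr22_fwd, chr22_rec))
  count9_lost <- length(setdiff(0:(len - 1), union(chr9_fwd, chr9_rec)))
  count9_dup <- length(intersect(chr9_fwd, chr9_rec))
  c(delta22 = count22_lost - count22_dup,
    delta9 = count9_lost - count9_dup)
}

# Build a junction instance with a planted structure for classifier
# tests: returns refs, the fusion string and the intended truth. The
# homology trick mirrors molecular reality: the shared bases exist in
# both references at the crossover.
make_junction_instance <- function(mech = c("blunt", "microhomology", "insertion"),
                                   h = 4, ins = "GG", flank = 40,
                                   ref_len = 400) {
  mech <- match.arg(mech)
  repeat {
    refA <- random_dna_str(ref_len)
    refB <- random_dna_str(ref_len)
    i22 <- ref_len %/% 2
    i9 <- ref_len %/% 2
    if (mech == "microhomology") {
      substr(refB, i9 - h + 1, i9) <- substr(refA, i22 - h + 2, i22 + 1)
    }
    a_next <- substr(refA, i22 + 2, i22 + 2)
    b_first <- substr(refB, i9 + 1, i9 + 1)
    b_prev <- substr(refB, i9, i9)
    a_last <- substr(refA, i22 + 1, i22 + 1)
    boundary_ok <- switch(mech,
      blunt = b_prev != a_last && a_next != b_first,
      microhomology = substr(refB, i9 - h, i9 - h) !=
          substr(refA, i22 - h + 1, i22 - h + 1) && a_next != b_first,
      insertion = substr(ins, 1, 1) != a_next &&
          substr(ins, nchar(ins), nchar(ins)) != b_prev &&
          b_prev != a_last)
    if (boundary_ok) break
  }
  middle <- if (mech == "insertion") ins else ""
  fusion <- paste0(substr(refA, i22 - flank + 2, i22 + 1), middle,
                   substr(refB, i9 + 1, i9 + flank))
  list(refA = refA, refB = refB, fusion = fusion, i22 = i22, i9 = i9,
       h = if (mech == "microhomology") h else 0L,
       ins = middle, mech = mech,
       startA = i22 - flank + 1, endB = i9 + flank)
}

# Small simulated world shared by several test files (kept modest so
# the default suite stays fast).
sim_world <- function(n = 60, seed = 42, ...) {
  ref <- make_toy_reference(seed = seed)
  params <- sim_params(n_patients = n, seed = seed, ...)
  sim <- simulate_cohort(params, ref)
  sim$refA <- sim$refs[["chr22_toy"]]
  sim$refB <- sim$refs[["chr9_toy"]]
  sim
}
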