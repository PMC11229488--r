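# Synthetic translocation cohorts with exact ground truth.
#
# The generator emulates the salient features of genomic BCR::ABL1
# cohorts: non-uniform per-locus breakpoint densities that differ
# between CML and ALL, a junction-mechanism mixture dominated by
# NHEJ signatures (microhomology ~48.6%, blunt ~36.6%, untemplated
# insertion ~12.4%), reciprocal fusions that are mostly balanced with
# rare large (>10 kbp) deletions/duplications, and optional planted
# motifs in the toy references.
#
# Ground truth is exact by construction: microhomologies are realized by
# injecting the required shared k-mer into the chr9-analog reference
# immediately 5' of the breakpoint, and junction-adjacent boundary bases
# are rejection-sampled so no accidental homology or templated extension
# can blur a mechanism call.

#' Simulation parameters for [simulate_cohort()]
#'
#' Defaults describe the study conditions the generator is meant to
#' emulate: the published junction-mechanism mixture of BCR::ABL1
#' cohorts (48.6% microhomology with median length 1 bp and range
#' 1-71 bp, 36.6% blunt, 12.4% insertion with median ~2.5 bp and range
#' 1-42 bp), group-dependent locus usage (Major-dominated CML,
#' minor-dominated ALL), opposing 5'/3' density skews for CML vs ALL in
#' the ABL1-analog region, and reciprocal fusions that are usually
#' balanced to within a few bases, with a rare >10 kbp
#' deletion/duplication tail.
#'
#' @param n_patients cohort size.
#' @param mech_probs probabilities of (microhomology, blunt, insertion).
#'   Renormalized to sum to 1: published mechanism percentages usually
#'   leave a small remainder of complex events, which this generator
#'   does not emit.
#' @param mh_geom_p geometric parameter of the microhomology length
#'   (`1 + rgeom(mh_geom_p)`, so `p = 0.5` gives median 1).
#' @param mh_max truncation cap for microhomology length (bases).
#' @param ins_geom_p geometric parameter of insertion length
#'   (`1 + rgeom(ins_geom_p)`; the default `1 - sqrt(0.5)` puts the
#'   median at the 2/3 boundary, i.e. ~2.5).
#' @param ins_max truncation cap for insertion length (bases).
#' @param p_cml probability a patient is in the CML-analog group.
#' @param locus_probs per-group probabilities over the chr22 loci
#'   (`minor`, `Major`, `micro`).
#' @param density_profiles per-region breakpoint density weights over 10
#'   equal sub-bins; either one numeric vector per region (both groups)
#'   or `list(CML = ..., ALL = ...)`.
#' @param adult_minor_profile density weights used for ALL-group
#'   patients older than 16 in the minor region; encodes a moderate age
#'   effect on the minor-region distribution. Set to `NULL` for no age
#'   effect.
#' @param p_imbalance probability, per chromosome, that the reciprocal
#'   fusion carries a nonzero deletion/duplication on that chromosome;
#'   `0` forces perfectly balanced translocations.
#' @param imbalance_class_probs probabilities of the imbalance size
#'   classes `1`, `2-100`, `101-10000`, `10001-size_cap` bases (sizes
#'   log-uniform within a class).
#' @param p_deletion probability a nonzero imbalance is a deletion
#'   (positive delta) rather than a duplication.
#' @param imbalance_size_cap largest drawable imbalance (bases); keep
#'   well inside the toy region width.
#' @param flank flank length (bases) on each side of the junction in the
#'   emitted `junction_seq`; must exceed `mh_max`.
#' @param seed master seed; all stage randomness derives from it via
#'   [split_seed()].
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_patients = 500L,
                       mech_probs = c(microhomology = 0.486,
                                      blunt = 0.366,
                                      insertion = 0.124),
                       mh_geom_p = 0.5,
                       mh_max = 71L,
                       ins_geom_p = 1 - sqrt(0.5),
                       ins_max = 42L,
                       p_cml = 0.466,
                       locus_probs = list(
                         CML = c(minor = 0.01, Major = 0.98, micro = 0.01),
                         ALL = c(minor = 0.755, Major = 0.24, micro = 0.005)),
                       density_profiles = list(
                         minor_BCR = c(0.35, 0.4, 0.5, 0.6, 0.7,
                                       0.9, 1.1, 1.4, 2.2, 1.85),
                         Major_BCR = list(
                           CML = c(1.8, 1.6, 1.4, 1.2, 1.0, 0.8, 0.6, 0.6, 0.5, 0.5),
                           ALL = c(1.3, 1.2, 1.1, 1.0, 1.0, 0.9, 0.9, 0.9, 0.85, 0.85)),
                         micro_BCR = rep(1, 10),
                         ABL1 = list(
                           CML = seq(1.4, 0.6, length.out = 10),
                           ALL = seq(0.6, 1.4, length.out = 10))),
                       adult_minor_profile = c(0.675, 0.7, 0.75, 0.8, 0.85,
                                               0.95, 1.05, 1.2, 1.6, 1.425),
                       p_imbalance = 0.816,
                       imbalance_class_probs = c(0.165, 0.59, 0.165, 0.08),
                       p_deletion = 0.75,
                       imbalance_size_cap = 40000L,
                       flank = 100L,
                       seed = 1L) {
  .check_prob(mech_probs, "mech_probs")
  # published mechanism percentages typically leave a small remainder of
  # complex/unclassifiable events; renormalize over the three NHEJ
  # classes as long as the total is close to 1
  if (abs(sum(mech_probs) - 1) > 0.1) {
    .stop_format("mech_probs must sum to (approximately) 1")
  }
  mech_probs <- mech_probs / sum(mech_probs)
  if (length(mech_probs) != 3L) .stop_format("mech_probs needs 3 entries")
  names(mech_probs) <- c("microhomology", "blunt", "insertion")
  .check_prob(c(p_cml, p_imbalance, p_deletion, mh_geom_p, ins_geom_p),
              "probability parameters")
  .check_prob(imbalance_class_probs, "imbalance_class_probs")
  if (abs(sum(imbalance_class_probs) - 1) > 1e-8) {
    .stop_format("imbalance_class_probs must sum to 1")
  }
  if (!.is_count(n_patients, 1L)) .stop_format("n_patients must be >= 1")
  if (flank <= mh_max) .stop_format("flank must exceed mh_max")
  for (g in c("CML", "ALL")) {
    lp <- locus_probs[[g]]
    if (is.null(lp) || abs(sum(lp) - 1) > 1e-8) {
      .stop_format("locus_probs$%s must sum to 1", g)
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), mech_probs = mech_probs,
         mh_geom_p = mh_geom_p, mh_max = as.integer(mh_max),
         ins_geom_p = ins_geom_p, ins_max = as.integer(ins_max),
         p_cml = p_cml, locus_probs = locus_probs,
         density_profiles = density_profiles,
         adult_minor_profile = adult_minor_profile,
         p_imbalance = p_imbalance,
         imbalance_class_probs = imbalance_class_probs,
         p_deletion = p_deletion,
         imbalance_size_cap = as.integer(imbalance_size_cap),
         flank = as.integer(flank), seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Generate toy partner references
#'
#' Builds random plus-strand sequences for the toy chr22 and chr9
#' analogs, optionally planting motif occurrences verbatim at stated
#' positions, and returns the matching [toy_catalog()]. Deterministic
#' for a fixed seed.
#'
#' @param seed integer seed.
#' @param region_lengths named lengths (bases) of the toy chromosomes;
#'   names become FASTA record names. Must be >= 20 kbp each.
#' @param planted_motifs optional list of
#'   `list(pattern =, chrom =, positions =)` entries; `positions` are
#'   0-based offsets at which `pattern` is written into the sequence.
#' @return a list with `sequences` (named character vector), `motifs`
#'   (BED-style `data.frame` of planted occurrences) and `catalog` (the
#'   matching [toy_catalog()]).
#' @export
#' @examples
#' ref <- make_toy_reference(seed = 1)
#' nchar(ref$sequences)
make_toy_reference <- function(seed = 1L,
                               region_lengths = c(chr22_toy = 80000L,
                                                  chr9_toy = 120000L),
                               planted_motifs = NULL) {
  if (is.null(names(region_lengths)) || any(!nzchar(names(region_lengths)))) {
    .stop_format("region_lengths must be named")
  }
  if (any(region_lengths < 1000)) .stop_format("toy sequences must be >= 1 kbp")
  set.seed(split_seed(seed, 101L))
  seqs <- vapply(region_lengths, .random_dna, character(1L))
  names(seqs) <- names(region_lengths)
  bed <- NULL
  if (!is.null(planted_motifs)) {
    rows <- list()
    for (m in planted_motifs) {
      pattern <- toupper(m$pattern)
      chrom <- m$chrom
      if (!chrom %in% names(seqs)) .stop_format("unknown chromosome '%s'", chrom)
      if (nchar(pattern) > nchar(seqs[[chrom]])) {
        .stop_format("motif '%s' longer than sequence '%s'", pattern, chrom)
      }
      for (pos in m$positions) {
        if (pos < 0 || pos + nchar(pattern) > nchar(seqs[[chrom]])) {
          .stop_format("planted position %d out of range for '%s' on %s",
                       pos, pattern, chrom)
        }
        substr(seqs[[chrom]], pos + 1L, pos + nchar(pattern)) <- pattern
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + nchar(pattern),
          name = pattern, score = 0, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    bed <- do.call(rbind, rows)
  }
  if (is.null(bed)) {
    bed <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  cat_lens <- region_lengths[c("chr22_toy", "chr9_toy")]
  catalog <- if (!anyNA(cat_lens)) {
    toy_catalog(cat_lens[[1L]], cat_lens[[2L]])
  } else NULL
  list(sequences = seqs, motifs = bed, catalog = catalog)
}

# truncated shifted geometric: 1 + rgeom, capped
.rlen <- function(n, p, cap) {
  pmin(1L + stats::rgeom(n, p), cap)
}

#' Draw breakpoint positions from a piecewise-constant density
#'
#' Samples coordinates over a region from a 10-bin (or any-bin)
#' piecewise-constant density -- the same machinery the cohort
#' simulator uses for its per-group breakpoint profiles. Useful for
#' power and calibration studies of the distribution tests.
#'
#' @param n number of positions.
#' @param region a [genomic_region()].
#' @param weights non-negative bin weights over equal sub-bins of the
#'   region (they need not sum to 1); a single value gives the uniform
#'   density.
#' @param seed optional integer seed.
#' @return numeric vector of `n` 0-based positions inside the region.
#' @export
#' @examples
#' reg <- genomic_region("demo", "chr1", 0, 10000, "toy")
#' x <- sample_breakpoints(400, reg, seq(1.4, 0.6, length.out = 10), seed = 1)
sample_breakpoints <- function(n, region, weights = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(split_seed(seed, 505L))
  if (length(weights) == 1L) weights <- rep(weights, 10L)
  .sample_profile(n, region, weights)
}

# draw n positions from a piecewise-constant density over a region
.sample_profile <- function(n, region, weights) {
  nb <- length(weights)
  if (any(weights < 0) || sum(weights) <= 0) {
    .stop_format("density weights for %s must be non-negative and not all zero",
                 region$name)
  }
  edges <- round(seq(region$start, region$end, length.out = nb + 1L))
  bins <- sample.int(nb, n, replace = TRUE, prob = weights)
  lo <- edges[bins]
  hi <- edges[bins + 1L] - 1
  floor(stats::runif(n, lo, hi + 1))
}

.profile_for <- function(params, region_name, group, age = NA) {
  prof <- params$density_profiles[[region_name]]
  if (is.null(prof)) return(rep(1, 10))
  if (is.list(prof)) prof <- prof[[group]]
  if (region_name == "minor_BCR" && !is.null(params$adult_minor_profile) &&
      identical(group, "ALL") && !is.na(age) && age > 16) {
    prof <- params$adult_minor_profile
  }
  prof
}

# draw one signed imbalance delta (0 = balanced on this chromosome)
.draw_delta <- function(params) {
  if (stats::runif(1) >= params$p_imbalance) return(0)
  cls <- sample.int(4L, 1L, prob = params$imbalance_class_probs)
  size <- switch(cls,
    `1` = 1,
    `2` = round(exp(stats::runif(1, log(2), log(100)))),
    `3` = round(exp(stats::runif(1, log(101), log(10000)))),
    `4` = round(exp(stats::runif(1, log(10001),
                                 log(params$imbalance_size_cap)))))
  sgn <- if (stats::runif(1) < params$p_deletion) 1 else -1
  sgn * size
}

#' Simulate a translocation cohort with known ground truth
#'
#' Draws a cohort of patients, each with a diagnosis group (CML/ALL
#' analog), age, sex, chr22 locus, a forward breakpoint pair, a junction
#' mechanism with its length, and a reciprocal breakpoint pair with a
#' drawn per-chromosome imbalance. Junction sequences are emitted with
#' `flank` reference bases on each side.
#'
#' Microhomologies are guaranteed exactly: the required shared k-mer is
#' written into the chr9-analog reference immediately 5' of the chr9
#' breakpoint, and junction-boundary bases are rejection-sampled so that
#' no accidental homology extension or templated insertion can occur.
#' Because this edits the reference, downstream stages must use the
#' `refs` element returned here, not the pre-simulation sequences.
#' Already-used junction neighborhoods are locked, and sites whose
#' constraints cannot be met are redrawn (`retries` in the truth table
#' counts redraws).
#'
#' @param params a [sim_params()] object.
#' @param ref a list from [make_toy_reference()], or any list with
#'   `sequences` (named character vector, plus-strand) and `catalog`
#'   (a [region_catalog()] whose chroms name those sequences).
#' @return a list with
#'   \describe{
#'     \item{truth}{per-patient ground truth `data.frame`: drawn and
#'       canonical coordinates (0-based), mechanism, lengths, reciprocal
#'       coordinates, signed `delta22`/`delta9`, group, age, sex, locus,
#'       junction sequences, and retry counts.}
#'     \item{cohort}{the public cohort table (class `fusion_cohort`,
#'       0-based internally) as [read_cohort_table()] would return it.}
#'     \item{refs}{the (possibly edited) reference sequences actually
#'       underlying the cohort.}
#'     \item{catalog}{the region catalog used.}
#'   }
#' @export
simulate_cohort <- function(params = sim_params(), ref = make_toy_reference()) {
  stopifnot(inherits(params, "sim_params"))
  seqs <- ref$sequences
  catalog <- ref$catalog
  if (is.null(seqs) || is.null(catalog)) {
    .stop_format("'ref' must provide $sequences and $catalog")
  }
  abl <- catalog$regions[["ABL1"]]
  chr22_name <- catalog$regions[["minor_BCR"]]$chrom
  chr9_name <- abl$chrom
  if (!chr22_name %in% names(seqs) || !chr9_name %in% names(seqs)) {
    .stop_format("reference sequences must include '%s' and '%s'",
                 chr22_name, chr9_name)
  }
  refA_raw <- .seq_raw(seqs[[chr22_name]])   # chr22 analog, read-only
  refB_raw <- .seq_raw(seqs[[chr9_name]])    # chr9 analog, edited in place
  lenB <- length(refB_raw)
  margin <- params$flank + 160L              # room for flanks and reads
  for (r in catalog$regions) {
    chrom_len <- if (r$chrom == chr22_name) length(refA_raw) else lenB
    if (r$start < margin || r$end > chrom_len - margin) {
      .stop_format("region %s must keep >= %d bases from the '%s' ends",
                   r$name, margin, r$chrom)
    }
  }
  locked <- logical(lenB)                    # chr9 bases no later patient may touch
  set.seed(split_seed(params$seed, 202L))

  n <- params$n_patients
  group <- ifelse(stats::runif(n) < params$p_cml, "CML", "ALL")
  age <- ifelse(group == "CML",
                ifelse(stats::runif(n) < 0.44,
                       stats::runif(n, 2, 17), stats::runif(n, 18, 75)),
                ifelse(stats::runif(n) < 0.68,
                       stats::runif(n, 1, 16), stats::runif(n, 17, 70)))
  age <- round(age, 1)
  sex <- ifelse(stats::runif(n) < 0.55, "M", "F")
  mech <- sample(names(params$mech_probs), n, replace = TRUE,
                 prob = params$mech_probs)
  locus <- character(n)
  for (g in c("CML", "ALL")) {
    idx <- which(group == g)
    lp <- params$locus_probs[[g]]
    locus[idx] <- sample(names(lp), length(idx), replace = TRUE, prob = lp)
  }

  base_at <- function(raw, pos0) raw[pos0 + 1L]     # 0-based accessor
  max_retries <- 200L

  truth <- vector("list", n)
  for (i in seq_len(n)) {
    reg22 <- catalog$regions[[.locus_region_name(locus[i])]]
    w22 <- .profile_for(params, reg22$name, group[i], age[i])
    w9 <- .profile_for(params, "ABL1", group[i], age[i])
    h <- if (mech[i] == "microhomology") .rlen(1L, params$mh_geom_p, params$mh_max) else 0L
    ins_len <- if (mech[i] == "insertion") .rlen(1L, params$ins_geom_p, params$ins_max) else 0L

    placed <- FALSE
    retries <- 0L
    while (!placed) {
      if (retries > max_retries) {
        .stop_format("patient %d: could not place junction after %d retries",
                     i, max_retries)
      }
      i22 <- .sample_profile(1L, reg22, w22)
      i9 <- .sample_profile(1L, abl, w9)
      # chr9 neighborhood this patient depends on: h written bases plus
      # one boundary base on each side plus the first retained base
      lock_lo <- i9 - h - 1L
      lock_hi <- i9 + 1L
      if (any(locked[(lock_lo + 1L):(lock_hi + 1L)])) {
        retries <- retries + 1L; next
      }
      if (mech[i] == "microhomology") {
        # inject the shared k-mer: B[i9-h .. i9-1] := A[i22-h+1 .. i22]
        hom <- refA_raw[(i22 - h + 2L):(i22 + 1L)]
        refB_raw[(i9 - h + 1L):i9] <- hom
        ok <- base_at(refB_raw, i9 - h - 1L) != base_at(refA_raw, i22 - h) &&
          base_at(refB_raw, i9) != base_at(refA_raw, i22 + 1L)
        if (!ok) { retries <- retries + 1L; next }   # injected bases are
        # harmless leftovers; the site is redrawn and nothing was locked
      } else {
        # forbid accidental homology at an intended blunt/insertion join
        ok <- base_at(refB_raw, i9 - 1L) != base_at(refA_raw, i22) &&
          base_at(refB_raw, i9) != base_at(refA_raw, i22 + 1L)
        if (!ok) { retries <- retries + 1L; next }
      }
      # reciprocal coordinates from drawn per-chromosome imbalances
      rec_ok <- FALSE
      for (try_rec in 1:50) {
        d22 <- .draw_delta(params)
        d9 <- .draw_delta(params)
        i22r <- i22 + 1L + d22
        i9r <- i9 - 1L - d9
        if (i22r >= reg22$start && i22r < reg22$end &&
            i9r >= abl$start && i9r < abl$end &&
            !any(locked[(i9r):(i9r + 2L)])) {
          rec_ok <- TRUE; break
        }
      }
      if (!rec_ok) { retries <- retries + 1L; next }
      locked[(lock_lo + 1L):(lock_hi + 1L)] <- TRUE
      locked[(i9r):(i9r + 2L)] <- TRUE       # reciprocal boundary stays stable
      placed <- TRUE
    }
    ins_seq <- ""
    if (mech[i] == "insertion") {
      # untemplated bases: ends must differ from the templated
      # continuation on each side, or the insertion would be shorter
      repeat {
        ins_chars <- sample(DNA_BASES, ins_len, replace = TRUE)
        first_ok <- charToRaw(ins_chars[1L]) != base_at(refA_raw, i22 + 1L)
        last_ok <- charToRaw(ins_chars[ins_len]) != base_at(refB_raw, i9 - 1L)
        if (first_ok && last_ok) break
      }
      ins_seq <- paste(ins_chars, collapse = "")
    }
    truth[[i]] <- data.frame(
      patient_id = sprintf("P%04d", i),
      group = group[i], age = age[i], sex = sex[i], locus = locus[i],
      mechanism = mech[i], mh_len = h, ins_len = ins_len, ins_seq = ins_seq,
      pos22 = i22, pos9 = i9,
      pos22_rec = i22r, pos9_rec = i9r,
      delta22 = d22, delta9 = d9,
      canonical_pos22 = i22 - h, canonical_pos9 = i9 - h,
      retries = retries,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)

  # emit junction sequences from the final references
  fl <- params$flank
  seq_between <- function(raw, lo0, hi0) rawToChar(raw[(lo0 + 1L):(hi0 + 1L)])
  truth$junction_seq <- vapply(seq_len(n), function(i) {
    paste0(seq_between(refA_raw, truth$pos22[i] - fl + 1L, truth$pos22[i]),
           truth$ins_seq[i],
           seq_between(refB_raw, truth$pos9[i], truth$pos9[i] + fl - 1L))
  }, character(1L))
  truth$rec_junction_seq <- vapply(seq_len(n), function(i) {
    paste0(seq_between(refB_raw, truth$pos9_rec[i] - fl + 1L, truth$pos9_rec[i]),
           seq_between(refA_raw, truth$pos22_rec[i], truth$pos22_rec[i] + fl - 1L))
  }, character(1L))

  seqs[[chr9_name]] <- rawToChar(refB_raw)
  cohort <- data.frame(
    patient_id = truth$patient_id,
    diagnosis = truth$group,
    age_years = truth$age,
    sex = truth$sex,
    locus = truth$locus,
    pos22 = truth$pos22,
    pos9 = truth$pos9,
    pos22_rec = truth$pos22_rec,
    pos9_rec = truth$pos9_rec,
    junction_seq = truth$junction_seq,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("fusion_cohort", class(cohort))
  attr(cohort, "catalog") <- catalog
  list(truth = truth, cohort = cohort, refs = seqs, catalog = catalog)
}

#' Simulate junction-spanning reads
#'
#' Emits error-prone single-end reads spanning each simulated junction.
#' The split point is uniform across the junction subject to at least
#' `min_anchor` reference-matching bases on each side; substitution
#' errors are applied independently per base. Deterministic for a fixed
#' seed.
#'
#' @param truth the `truth` table from [simulate_cohort()].
#' @param refs the `refs` element from the same [simulate_cohort()] run.
#' @param catalog the matching region catalog.
#' @param read_len read length (bases); must be at least
#'   `2 * min_anchor + max insertion length` in the cohort.
#' @param n_reads_per_junction reads emitted per junction.
#' @param error_rate per-base substitution probability.
#' @param min_anchor minimum reference-derived bases on each side of the
#'   junction within a read.
#' @param include_reciprocal also emit reads over each reciprocal
#'   (chr9 -> chr22) junction, named `<patient>_rec_r<i>`.
#' @param seed integer seed.
#' @param out_fastq optional path; when given the reads are also written
#'   as FASTQ (constant qualities).
#' @return a named character vector of reads (names
#'   `<patient>_r<i>` / `<patient>_rec_r<i>`), invisibly written to
#'   `out_fastq` when requested.
#' @export
simulate_reads <- function(truth, refs, catalog,
                           read_len = 150L, n_reads_per_junction = 20L,
                           error_rate = 0, min_anchor = 12L,
                           include_reciprocal = FALSE,
                           seed = 1L, out_fastq = NULL) {
  if (!.is_count(n_reads_per_junction)) {
    .stop_format("n_reads_per_junction must be a non-negative count")
  }
  .check_prob(error_rate, "error_rate")
  chr22_name <- catalog$regions[["minor_BCR"]]$chrom
  chr9_name <- catalog$regions[["ABL1"]]$chrom
  refA <- refs[[chr22_name]]
  refB <- refs[[chr9_name]]
  if (read_len < 2L * min_anchor + max(truth$ins_len)) {
    .stop_format("read_len must be >= 2 * min_anchor + the longest insertion (%d)",
                 max(truth$ins_len))
  }
  set.seed(split_seed(seed, 303L))
  n <- nrow(truth)
  reads <- character(0)
  if (n_reads_per_junction > 0L && n > 0L) {
    emit <- function(window, n_left, ins_len, id_prefix) {
      # window = read_len left-side bases + insertion + read_len right-side
      # bases around the junction; a = left-side bases kept in the read
      a <- sample(seq.int(min_anchor, read_len - ins_len - min_anchor),
                  n_reads_per_junction, replace = TRUE)
      starts <- n_left - a + 1L
      r <- substring(window, starts, starts + read_len - 1L)
      names(r) <- sprintf("%s_r%03d", id_prefix, seq_len(n_reads_per_junction))
      r
    }
    out <- vector("list", n * (1L + include_reciprocal))
    k <- 0L
    for (i in seq_len(n)) {
      i22 <- truth$pos22[i]; i9 <- truth$pos9[i]
      window <- paste0(substr(refA, i22 - read_len + 2L, i22 + 1L),
                       truth$ins_seq[i],
                       substr(refB, i9 + 1L, i9 + read_len))
      if (nchar(window) < read_len) {
        .stop_format("patient %s: fused sequence shorter than read_len",
                     truth$patient_id[i])
      }
      k <- k + 1L
      out[[k]] <- emit(window, read_len, truth$ins_len[i], truth$patient_id[i])
      if (include_reciprocal) {
        i22r <- truth$pos22_rec[i]; i9r <- truth$pos9_rec[i]
        window_r <- paste0(substr(refB, i9r - read_len + 2L, i9r + 1L),
                           substr(refA, i22r + 1L, i22r + read_len))
        k <- k + 1L
        out[[k]] <- emit(window_r, read_len, 0L,
                         paste0(truth$patient_id[i], "_rec"))
      }
    }
    reads <- unlist(out)
    if (error_rate > 0) {
      mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                    nrow = read_len)
      hit <- which(stats::runif(length(mat)) < error_rate)
      if (length(hit)) {
        # substitute with one of the three other bases, uniformly
        repl <- vapply(mat[hit], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1L))
        mat[hit] <- repl
      }
      nm <- names(reads)
      reads <- apply(mat, 2L, paste, collapse = "")
      names(reads) <- nm
    }
  }
  if (!is.null(out_fastq)) .write_fastq(reads, out_fastq)
  reads
}
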