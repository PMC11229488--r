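---
title: "Methods: simulating and analyzing BCR::ABL1-type genomic breakpoints"
author: "breakfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing BCR::ABL1-type genomic breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakfusion)
```

## The problem

The t(9;22)(q34;q11) translocation — the Philadelphia chromosome — fuses
*BCR* on chromosome 22 with *ABL1* on chromosome 9. It defines chronic
myeloid leukemia (CML) and marks a high-risk subset of acute
lymphoblastic leukemia (ALL). The DNA breaks land in large, mostly
intronic regions: the ~71.5 kbp *minor* breakpoint cluster region in
*BCR* intron 1 (p190 fusion protein, ALL-dominated), the ~2.9 kbp
*Major* region spanning introns 13–14 (p210, CML-dominated), the small
*micro* region (p230), and the ~155 kbp *ABL1* breakpoint area upstream
of exon 2. Characterizing a patient's genomic junction at nucleotide
resolution answers three kinds of questions:

1. **Where do the breaks fall**, and does the positional distribution
   differ between disease groups, sexes, or ages?
2. **How were the ends joined** — the junction's primary structure
   (shared microhomology, clean blunt join, or untemplated insertion)
   is the signature of the repair pathway, classically non-homologous
   end joining (NHEJ).
3. **Is the translocation balanced** — comparing the forward
   (BCR::ABL1) and reciprocal (ABL1::BCR) junctions of one patient
   exposes deletions and duplications on both derivative chromosomes.

`breakfusion` implements this analysis stack as reusable, tested
components, together with a synthetic-data generator so that every
stage can be validated end to end against known ground truth without
any external download.

## Coordinate bookkeeping

Internally every position is a 0-based index of a base; cohort TSV
files are 1-based (see `?breakpoint_coordinates`). Both partner genes
are modeled on the plus strand, which is true for *BCR* and *ABL1*;
strand generality is deliberately out of scope. A forward junction is
reported as (last chr22 base retained, first chr9 base retained); a
reciprocal junction as (last chr9 base retained, first chr22 base
retained). Under this convention adjacency — `pos22_rec = pos22_fwd + 1`
and `pos9_fwd = pos9_rec + 1` — is the perfectly balanced case, and the
signed per-chromosome imbalance is

```
delta22 = pos22_rec - pos22_fwd - 1     (deletion > 0, duplication < 0)
delta9  = pos9_fwd  - pos9_rec  - 1
```

One consequence worth stating: "exchange the forward and reciprocal
roles" only negates the deltas after the junction base is renamed to
its new role (a first-retained coordinate becomes a last-retained one,
shifting it by one); the test suite pins this down.

## Junction decomposition

`classify_junction()` decomposes a fusion sequence `F` against the two
partner references using two maximal contiguous matches: `p`, the
longest prefix of `F` matching partner A from its aligned start, and
`s`, the longest suffix matching partner B up to its aligned end. Then

* `p + s == |F|` — blunt join;
* `p + s > |F|` — microhomology of `h = p + s − |F|` bases shared by
  both partners at the crossover; the crossover is ambiguous over
  `h + 1` equivalent placements and is canonicalized to the *leftmost*
  (5'-most on partner A), the usual structural-variant normalization.
  Published breakpoint tables rarely state their convention, so any
  ±1 bp / ±100 bp window comparison is convention-stable only up to
  `h`; `h` is small (median 1) in this disease context, so the effect
  is marginal but documented.
* `p + s < |F|` — untemplated insertion `F[p+1 .. |F|−s]`, bases
  matching neither flank.

A tie between microhomology and insertion is impossible (the
inequalities are exclusive), and the decomposition provably reproduces
`F` when reassembled — both are asserted in tests, and the
decomposition is checked against a brute-force oracle that enumerates
every (crossover, insertion) explanation on 10,000 random junctions.

Anchoring uses an exact seed of `min_anchor` bases on each side
(default 12). Junctions that cannot anchor both flanks — for example
complex events with inserted material from elsewhere in the genome —
are rejected as *unanchored* rather than guessed, mirroring how complex
BCR/ABL1 rearrangements (chromosome-9 fragments inserted into *BCR*,
kilobase-scale third-chromosome insertions) are flagged rather than
resolved. IUPAC ambiguity codes in references count as mismatches,
keeping homology calls conservative.

## The split-read caller

`call_fusion()` is a deterministic, desk-scale seed-and-extend caller
for captured breakpoint regions (references of at most a few hundred
kbp — the scale at which an exact k-mer index is trivially feasible).
Per read: exact `min_anchor`-mer seeds place the read prefix on partner
A and suffix on partner B (reads whose anchors run B→A are skipped and
recovered by re-running with swapped references); the split minimizing
(mismatches, insert length) is chosen, leftmost on ties; the implied
crossover is canonicalized against the references. Votes are clustered
within ±3 bases on both coordinates (absorbing canonicalization jitter
from sequencing errors), a majority consensus junction is rebuilt from
the references plus the modal insert (per-column majority), and the
consensus is classified by `classify_junction()`, whose canonical
coordinates are reported. Calls below `min_support` (default 2) are
suppressed.

Design notes:

* The (mismatches, insert length) ordering is exact on error-free
  reads: the zero-mismatch minimal-insert explanation is unique and
  correct by construction. Its trade-off is that a sequencing error
  near the junction can be "explained" as a short zero-mismatch insert,
  so error-bearing reads occasionally vote for a shifted split. Majority
  voting keeps the patient-level call exact (100% at a 0.5% per-base
  error rate in the validation runs), but at `min_support = 2` such
  votes can occasionally coincide and emit a low-support spurious call
  alongside the true one. An insert-open penalty would suppress these
  at the cost of misdecomposing a few percent of genuine inserts whose
  bases resemble the reference; exactness on clean data was judged more
  valuable for a validation-oriented caller. Raise `min_support` for
  noisy data.
* Multi-mapping seeds discard the read (with a logged reason) rather
  than guessing; on random toy references this affects ~1% of reads.

## The synthetic-data generator

`simulate_cohort()` draws, per patient: a diagnosis-group analog
(CML/ALL), age and sex, a chr22 locus, breakpoint positions from
per-region piecewise-constant densities (10 equal sub-bins), a junction
mechanism with its length, and reciprocal coordinates with a drawn
per-chromosome imbalance. Its defaults *are* the study conditions the
package validates against, chosen once from the published
characteristics of genomic BCR::ABL1 cohorts:

* **Mechanism mixture** (0.486, 0.366, 0.124) for
  microhomology/blunt/insertion, renormalized over the three classes
  (published percentages leave a small remainder of complex events that
  the generator does not emit). Microhomology lengths are
  1 + geometric(0.5) capped at 71 (median 1); insertion lengths
  1 + geometric(1 − √0.5) capped at 42, placing the median at the 2/3
  boundary (≈ 2.5).
* **Locus usage**: Major-dominated CML (98%), minor-dominated ALL
  (75.5%), micro rare — the p210/p190 epidemiology.
* **Density profiles**: the minor region uses a pronounced 3'-skew
  (mass accumulating toward the end of intron 1) strong enough that a
  ~400-patient cohort decisively rejects uniformity, as real cohorts
  do; the ABL1 region uses opposing linear skews for the two groups
  (CML 5'-heavy, ALL 3'-heavy) with a population KS distance ≈ 0.2,
  set so the two-sample comparison at 400 + 400 patients has ≥ 90%
  power at α = 0.01 — slightly stronger than the shift real cohorts
  show, a deliberate choice so the calibration study is decisive.
* **Age effect**: ALL patients older than 16 draw minor-region
  positions from a profile halfway between the minor skew and uniform,
  a moderate shift detectable by the logistic screen at a few hundred
  patients (the acceptance run prints p in the few-per-thousand range),
  emulating the reported moderate age dependence.
* **Reciprocal balance**: each chromosome independently carries a
  nonzero imbalance with probability 0.816; sizes are a mixture of
  1 bp (16.5%), 2–100 bp (59%), 0.1–10 kbp (16.5%) and 10–40 kbp (8%),
  log-uniform within a class, deletions three times as likely as
  duplications. These values were back-calculated once from the
  published concordance fractions (≈ 3% perfectly balanced, ≈ 10%
  within ±1 bp on both genes, ≈ 80% within ±100 bp per gene, rare
  >10 kbp events). Because the toy regions are only 50–116 kbp wide,
  draws whose reciprocal coordinate would leave the region are
  resampled, which clips the large-event tail (≈ 4.5% of simulated
  patients carry a >10 kbp deletion vs ≈ 10% in real cohorts); the
  concordance windows are unaffected.

**Exact ground truth** is the generator's defining feature. A
microhomology of length `h` is realized by copying the `h` bases
5' of the chr22 breakpoint into the chr9-analog reference immediately
5' of the chr9 breakpoint — the shared sequence genuinely exists in
both references, as in real genomes. Junction-boundary bases are then
rejection-sampled so no *accidental* homology extension or templated
continuation can blur the call: an intended blunt join really has
`h = 0`, an intended insert's end bases match neither flank. Each
patient's touched chr9 neighborhood is locked so later patients cannot
disturb it; conflicting draws are resampled (retry counts are
reported). The cost of this design is that `simulate_cohort()` edits
the chr9-analog reference, so downstream stages must use the returned
`refs`. The benefit is that the classifier and caller can be held to
*100%* exact recovery rather than an approximate band.

`simulate_reads()` emits junction-spanning single-end reads with a
uniform split point (≥ `min_anchor` reference bases on each side) and
independent per-base substitution errors. It does not model capture
bias, indel errors, quality-score structure, PCR duplicates, or
off-target reads — so passing validations say the algorithms are
correct on reads whose only defect is substitution noise, not that the
caller is hardened against real capture-library artifacts.

All randomness flows from one master seed through the documented
splitting scheme `split_seed(seed, key)`.

## Distribution statistics

* `uniformity_test()` — Pearson chi-squared against the uniform
  expectation over equal-width bins. Published analyses rarely state
  their binning, which changes the p-value by orders of magnitude; the
  default ("auto") uses the largest bin count with expected count ≥ 5,
  capped at 100 — a standard validity rule stated explicitly so results
  are reproducible.
* `ks_compare()` — two-sample Kolmogorov–Smirnov; asymptotic p with
  effective n `nA·nB/(nA+nB)`, exact for small tie-free problems
  (`nA·nB ≤ 10000`). Binning-free, hence the preferred between-group
  comparison.
* `covariate_logit()` — single-predictor logistic regression of the
  binary covariate on the min–max-normalized position, with a
  likelihood-ratio p. With one predictor the LRT p is identical
  whichever direction the association is phrased. Complete separation
  is flagged rather than hidden; the LRT p is still returned.
* `proximity_enrichment()` — the observed statistic is the number of
  breakpoints within ± `window` (default 10) bases of any deduplicated
  motif hit; the null redraws breakpoints `n_perm` times, uniformly or
  from the binned empirical breakpoint profile. The density-matched
  null separates "motifs attract breaks" from "both motifs and breaks
  prefer the same neighborhood", which is exactly the confound in
  regions with strongly non-uniform break density. The Monte-Carlo p
  is `(1 + #{null ≥ obs})/(n_perm + 1)`: never below `1/(n_perm+1)`,
  deterministic per seed, and conservative when the expected hit count
  is very small (a discrete-statistic property worth remembering when
  interpreting calibration studies).

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses:
a 2,000-patient cohort for mixture recovery; 500 patients × 20
error-free reads and 200 patients × 30 reads at 0.5% error for the
caller; 10,000 random pairs for the reciprocal set-arithmetic oracle;
1,000 null replicates each for the chi-squared and permutation
calibrations (the latter with 200 breakpoints against a ~20%-coverage
hit mask, dense enough that discreteness does not masquerade as
miscalibration); 200 replicates of 400 + 400 for KS power; and 10,000
random junctions for the decomposition oracle. These sizes make every
check decisive at interactive runtimes on a single CPU.

## Known limitations

* Complex rearrangements (insertions from third chromosomes, local
  inversions) are only *flagged* (unanchored); their internal structure
  is out of scope.
* The toy genome is i.i.d. random sequence: no repeats, GC structure,
  or real RSS/motif landscape. Motif machinery is therefore validated
  on planted signals; biological conclusions require real references
  and a real motif catalog (the shipped `motifs.yaml` is an
  illustrative subset, clearly labeled).
* Chi-squared p-values depend on binning; cross-study comparisons
  should fix the binning rule first.
* The caller assumes plus-strand, single-junction reads from two small
  references; it is a validation-grade stand-in for a production
  capture-NGS pipeline, contract-equivalent on clean data rather than
  implementation-equivalent.
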