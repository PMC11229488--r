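Package: breakfusion
Title: Genomic Breakpoint Analysis for BCR::ABL1-Type Translocations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing the genomic breakpoints of reciprocal
    translocations such as t(9;22) BCR::ABL1. Provides a synthetic cohort
    and read simulator with known ground truth, a split-read fusion
    breakpoint caller, a junction primary-structure classifier
    (microhomology / blunt / untemplated insertion, the classic
    non-homologous end-joining signatures), reciprocal-fusion balance
    arithmetic (deletion and duplication sizing on both derivative
    chromosomes), breakpoint distribution statistics (chi-squared
    uniformity, two-sample Kolmogorov-Smirnov, logistic covariate
    screens), DNA motif and recombination-signal-sequence scanning with
    permutation-based proximity testing, and a static JSON/HTML report
    assembler.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
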