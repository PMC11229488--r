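# Motif scanning (IUPAC and RSS) and proximity permutation testing.

test_that("a palindromic pattern hits both strands at the same offset", {
  p <- motif_pattern("probe", "iupac", "ACGT")
  hits <- scan_iupac("AACGTT", p)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(1, 1))
  expect_equal(hits$end, c(5, 5))
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("planted motifs are found exactly where they were written", {
  offsets <- c(4000, 12000, 33000)
  r <- make_toy_reference(seed = 9, planted_motifs = list(
    list(pattern = "CACAGTG", chrom = "chr22_toy", positions = offsets)))
  p <- motif_pattern("hept", "iupac", "CACAGTG")
  hits <- scan_iupac(r$sequences[["chr22_toy"]], p)
  plus <- hits$start[hits$strand == "+"]
  expect_true(all(offsets %in% plus))
})

test_that("the fully degenerate pattern matches every window on each strand", {
  set.seed(6)
  seq <- random_dna_str(2000)
  p <- motif_pattern("any", "iupac", "NNNN")
  hits <- scan_iupac(seq, p)
  expect_equal(sum(hits$strand == "+"), 2000 - 3)   # |seq| - k + 1
  expect_equal(sum(hits$strand == "-"), 2000 - 3)
})

test_that("invalid IUPAC codes are rejected by name", {
  expect_error(motif_pattern("bad", "iupac", "ACXT"), "'X' at position 3")
})

test_that("mismatch allowances behave as counts, not fractions", {
  p0 <- motif_pattern("m0", "iupac", "ACGTACGT", max_mismatches = 0)
  p1 <- motif_pattern("m1", "iupac", "ACGTACGT", max_mismatches = 1)
  seq <- paste0("TTTTT", "ACGTACCT", "TTTTT")    # one mismatch at position 7
  expect_equal(sum(scan_iupac(seq, p0)$strand == "+"), 0L)
  expect_equal(sum(scan_iupac(seq, p1)$strand == "+"), 1L)
})

test_that("RSS scanning requires heptamer and nonamer at the spacer", {
  set.seed(7)
  filler12 <- "TGTGTGTGTGTG"
  good <- paste0(random_dna_str(50), "CACAGTG", filler12, "ACAAAAACC",
                 random_dna_str(50))
  rss <- motif_pattern("rss12", "rss", spacer = 12)
  hits <- scan_rss(good, rss)
  expect_equal(sum(hits$strand == "+"), 1L)
  expect_equal(hits$start[hits$strand == "+"], 50)
  expect_equal(hits$end[hits$strand == "+"], 50 + 7 + 12 + 9)

  hept_only <- paste0(random_dna_str(50), "CACAGTG", random_dna_str(50))
  expect_equal(nrow(scan_rss(hept_only, rss)), 0L)

  # one-mismatch nonamer: found with allowance 1, not with 0
  mut <- sub("ACAAAAACC", "ACAACAACC", good, fixed = TRUE)
  expect_equal(nrow(scan_rss(mut, motif_pattern("rss", "rss", spacer = 12,
                                                mm_nonamer = 0))), 0L)
  hits1 <- scan_rss(mut, motif_pattern("rss", "rss", spacer = 12,
                                       mm_nonamer = 1))
  expect_equal(sum(hits1$strand == "+"), 1L)

  # the reverse complement is reported on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(good)))
  hits_rc <- scan_rss(rc, rss)
  expect_equal(sum(hits_rc$strand == "-"), 1L)
  expect_equal(hits_rc$start[hits_rc$strand == "-"], 50)
})

test_that("breakpoints planted on motifs give a tiny permutation p", {
  reg <- genomic_region("demo", "chrT", 0, 20000, "toy")
  set.seed(8)
  motif_pos <- sort(sample(500:19000, 40))
  hits <- data.frame(start = motif_pos, end = motif_pos + 7)
  bp <- motif_pos[sample(40, 50, replace = TRUE)] + sample(-5:5, 50, TRUE)
  res <- proximity_enrichment(bp, hits, reg, window = 10, n_perm = 5000,
                              seed = 1)
  expect_lte(res$p_value, 0.001)
  expect_equal(res$observed, 50L)
})

test_that("the permutation p is bounded, deterministic, and dedup-invariant", {
  reg <- genomic_region("demo", "chrT", 0, 10000, "toy")
  set.seed(9)
  hits <- data.frame(start = c(100, 5000, 100), end = c(110, 5010, 110))
  bp <- runif(30, 0, 9999)
  r1 <- proximity_enrichment(bp, hits, reg, n_perm = 2000, seed = 3)
  r2 <- proximity_enrichment(bp, hits, reg, n_perm = 2000, seed = 3)
  r3 <- proximity_enrichment(bp, unique(hits), reg, n_perm = 2000, seed = 3)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$observed, r3$observed)
  expect_gte(r1$p_value, 1 / 2001)
  # no hits: observed 0, p = 1, flagged
  r0 <- proximity_enrichment(bp, hits[0, ], reg, n_perm = 2000, seed = 3)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$flag, "no_hits")
})

test_that("catalog-wide scanning applies a monotone BH correction", {
  r <- make_toy_reference(seed = 10,
                          region_lengths = c(chr22_toy = 30000,
                                             chr9_toy = 30000))
  motifs <- load_motifs(system.file("extdata", "motifs.yaml",
                                    package = "breakfusion"))
  expect_length(motifs, 6L)
  reg <- genomic_region("demo", "chr22_toy", 2000, 28000, "toy")
  set.seed(11)
  bp <- floor(runif(60, 2000, 28000))
  tab <- enrichment_scan(bp, motifs, r$sequences[["chr22_toy"]], reg,
                         n_perm = 1000, seed = 4)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$adjusted_p >= tab$p_value - 1e-12))
  # order preservation
  ord <- order(tab$p_value)
  expect_true(all(diff(tab$adjusted_p[ord]) >= -1e-12))
})

test_that("the density-matched null is available and calibrated at the peak", {
  reg <- genomic_region("demo", "chrT", 0, 20000, "toy")
  set.seed(12)
  # breakpoints concentrated 5'; motifs also 5': the uniform null calls
  # this proximity, the density-matched null largely explains it away
  bp <- floor(runif(80, 0, 4000))
  hits <- data.frame(start = seq(100, 3900, by = 200),
                     end = seq(100, 3900, by = 200) + 7)
  p_unif <- proximity_enrichment(bp, hits, reg, n_perm = 2000, seed = 5,
                                 null = "uniform")$p_value
  p_dens <- proximity_enrichment(bp, hits, reg, n_perm = 2000, seed = 5,
                                 null = "density")$p_value
  expect_lt(p_unif, 0.01)
  expect_gt(p_dens, p_unif)
})
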