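# Toy reference generation, cohort simulation ground truth, read
# simulation.

test_that("toy references are deterministic per seed and seed-sensitive", {
  r1 <- make_toy_reference(seed = 1)
  r2 <- make_toy_reference(seed = 1)
  r3 <- make_toy_reference(seed = 2)
  expect_identical(r1$sequences, r2$sequences)
  expect_false(identical(r1$sequences, r3$sequences))
  expect_equal(unname(nchar(r1$sequences)), c(80000L, 120000L))
})

test_that("planted motifs appear verbatim where the BED says", {
  r <- make_toy_reference(seed = 3, planted_motifs = list(
    list(pattern = "CACAGTG", chrom = "chr22_toy", positions = c(5000, 9000))))
  expect_equal(nrow(r$motifs), 2L)
  for (i in 1:2) {
    expect_equal(substr(r$sequences[["chr22_toy"]],
                        r$motifs$start[i] + 1, r$motifs$end[i]),
                 "CACAGTG")
  }
  expect_error(
    make_toy_reference(seed = 3, planted_motifs = list(
      list(pattern = strrep("A", 3000), chrom = "chr22_toy",
           positions = 2000000))),
    "out of range")
})

test_that("simulated ground truth is internally consistent", {
  sim <- sim_world(n = 150, seed = 31)
  tr <- sim$truth
  # one mechanism per patient, with mutually exclusive length fields
  expect_true(all(tr$mechanism %in% c("microhomology", "blunt", "insertion")))
  blunt <- tr$mechanism == "blunt"
  expect_true(all(tr$mh_len[blunt] == 0 & tr$ins_seq[blunt] == ""))
  expect_true(all(tr$mh_len[tr$mechanism == "microhomology"] >= 1))
  expect_true(all(nchar(tr$ins_seq[tr$mechanism == "insertion"]) >= 1))
  # imbalance conservation: deltas recomputed from emitted coordinates
  expect_equal(tr$pos22_rec - tr$pos22 - 1, tr$delta22)
  expect_equal(tr$pos9 - tr$pos9_rec - 1, tr$delta9)
  # positions fall in their locus regions
  for (i in seq_len(nrow(tr))) {
    reg <- sim$catalog$regions[[switch(tr$locus[i], minor = "minor_BCR",
                                       Major = "Major_BCR",
                                       micro = "micro_BCR")]]
    expect_true(tr$pos22[i] >= reg$start && tr$pos22[i] < reg$end)
  }
})

test_that("the classifier recovers every simulated junction exactly", {
  sim <- sim_world(n = 120, seed = 57)
  res <- classify_cohort(sim$cohort, sim$refA, sim$refB)
  expect_equal(res$n_classifiable, 120L)
  m <- merge(res$calls, sim$truth, by = "patient_id")
  expect_equal(m$mechanism.x, m$mechanism.y)
  expect_equal(m$mh_len.x, m$mh_len.y)
  expect_equal(m$ins_seq.x, m$ins_seq.y)
  expect_equal(m$posA, m$canonical_pos22)
  expect_equal(m$posB, m$canonical_pos9)
})

test_that("p_imbalance = 0 forces perfectly balanced translocations", {
  sim <- sim_world(n = 50, seed = 5, p_imbalance = 0)
  expect_true(all(sim$truth$delta22 == 0))
  expect_true(all(sim$truth$delta9 == 0))
  expect_true(all(sim$truth$pos22_rec == sim$truth$pos22 + 1))
  expect_true(all(sim$truth$pos9_rec == sim$truth$pos9 - 1))
})

test_that("a forced insertion matches neither reference flank", {
  sim <- sim_world(n = 1, seed = 77, mech_probs = c(0, 0, 1))
  tr <- sim$truth
  expect_equal(tr$mechanism, "insertion")
  ins <- tr$ins_seq
  # exhaustive flank comparison: the insert is not the templated
  # continuation of either partner at the junction
  contA <- substr(sim$refA, tr$pos22 + 2, tr$pos22 + 1 + nchar(ins))
  precB <- substr(sim$refB, tr$pos9 - nchar(ins) + 1, tr$pos9)
  expect_false(ins == contA)
  expect_false(ins == precB)
  expect_true(grepl(ins, tr$junction_seq, fixed = TRUE))
})

test_that("error-free reads are exact substrings of the fused sequence", {
  sim <- sim_world(n = 20, seed = 13)
  reads <- simulate_reads(sim$truth, sim$refs, sim$catalog,
                          n_reads_per_junction = 8, error_rate = 0, seed = 2)
  expect_length(reads, 160L)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    fused <- paste0(substr(sim$refA, tr$pos22 - 300 + 2, tr$pos22 + 1),
                    tr$ins_seq,
                    substr(sim$refB, tr$pos9 + 1, tr$pos9 + 300))
    mine <- reads[startsWith(names(reads), paste0(tr$patient_id, "_"))]
    expect_true(all(vapply(mine, function(r) grepl(r, fused, fixed = TRUE),
                           logical(1))))
  }
})

test_that("read simulation is deterministic and honors zero reads", {
  sim <- sim_world(n = 5, seed = 19)
  fq1 <- tempfile(fileext = ".fastq")
  fq2 <- tempfile(fileext = ".fastq")
  r1 <- simulate_reads(sim$truth, sim$refs, sim$catalog,
                       n_reads_per_junction = 5, error_rate = 0.01,
                       seed = 4, out_fastq = fq1)
  r2 <- simulate_reads(sim$truth, sim$refs, sim$catalog,
                       n_reads_per_junction = 5, error_rate = 0.01,
                       seed = 4, out_fastq = fq2)
  expect_identical(r1, r2)
  expect_identical(readLines(fq1), readLines(fq2))
  # zero reads per junction -> a valid empty FASTQ
  fq0 <- tempfile(fileext = ".fastq")
  r0 <- simulate_reads(sim$truth, sim$refs, sim$catalog,
                       n_reads_per_junction = 0, seed = 4, out_fastq = fq0)
  expect_length(r0, 0L)
  expect_true(file.exists(fq0))
  expect_length(read_junction_reads(fq0), 0L)
})

test_that("opposing 5'/3' group profiles induce a detectable KS shift", {
  params <- sim_params()
  abl <- toy_catalog()$regions$ABL1
  cml <- sample_breakpoints(400, abl, params$density_profiles$ABL1$CML, seed = 8)
  all_ <- sample_breakpoints(400, abl, params$density_profiles$ABL1$ALL, seed = 9)
  res <- ks_compare(cml, all_)
  expect_lt(res$p_value, 0.01)
})
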