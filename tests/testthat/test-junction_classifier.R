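# Junction decomposition: mechanism calls, canonicalization, oracle
# agreement.

test_that("a clean join with incompatible flanks is called blunt", {
  set.seed(11)
  inst <- make_junction_instance("blunt")
  call <- classify_junction(inst$fusion, inst$refA, inst$refB)
  expect_equal(call$mechanism, "blunt")
  expect_equal(call$mh_len, 0L)
  expect_equal(call$ins_seq, "")
  expect_equal(call$ambiguity_window, 1L)
  expect_equal(call$canonical_posA, inst$i22)
  expect_equal(call$canonical_posB, inst$i9)
})

test_that("a shared 4-mer yields h = 4 and a 5-placement ambiguity window", {
  set.seed(12)
  inst <- make_junction_instance("microhomology", h = 4)
  call <- classify_junction(inst$fusion, inst$refA, inst$refB)
  expect_equal(call$mechanism, "microhomology")
  expect_equal(call$mh_len, 4L)
  expect_equal(call$ambiguity_window, 5L)
  # exhaustive crossover oracle agrees on the window and placement
  orc <- oracle_decompose(inst$fusion, inst$refA, inst$refB,
                          inst$startA, inst$endB)
  expect_equal(orc$n_explanations_min_d, 5L)
  expect_equal(call$canonical_posA, orc$posA)
  expect_equal(call$canonical_posB, orc$posB)
})

test_that("bases matching neither flank are called as an untemplated insert", {
  set.seed(13)
  inst <- make_junction_instance("insertion", ins = "GG")
  call <- classify_junction(inst$fusion, inst$refA, inst$refB)
  expect_equal(call$mechanism, "insertion")
  expect_equal(call$ins_seq, "GG")
  expect_equal(call$mh_len, 0L)
  # flank-comparison oracle: the insert extends neither reference
  expect_false(substr(inst$refA, inst$i22 + 2, inst$i22 + 2) == "G" &&
                 substr(inst$refA, inst$i22 + 3, inst$i22 + 3) == "G")
  orc <- oracle_decompose(inst$fusion, inst$refA, inst$refB,
                          inst$startA, inst$endB)
  expect_equal(orc$ins_seq, "GG")
})

test_that("decomposition matches the brute-force oracle on random junctions", {
  set.seed(4321)
  n_cases <- 800
  mechs <- sample(c("blunt", "microhomology", "insertion"), n_cases,
                  replace = TRUE)
  for (i in seq_len(n_cases)) {
    h <- sample(1:10, 1)
    ins <- random_dna_str(sample(1:6, 1))
    inst <- make_junction_instance(mechs[i], h = h, ins = ins)
    call <- classify_junction(inst$fusion, inst$refA, inst$refB,
                              anchorA = inst$i22, anchorB = inst$i9)
    orc <- oracle_decompose(inst$fusion, inst$refA, inst$refB,
                            inst$startA, inst$endB)
    expect_equal(call$mechanism, orc$mechanism)
    expect_equal(call$mh_len, orc$mh_len)
    expect_equal(call$ins_seq, orc$ins_seq)
    expect_equal(call$canonical_posA, orc$posA)
    expect_equal(call$canonical_posB, orc$posB)
    # mutually exclusive mechanism invariants
    if (call$mechanism == "microhomology") {
      expect_true(call$mh_len >= 1L && call$ins_seq == "")
    } else if (call$mechanism == "insertion") {
      expect_true(call$mh_len == 0L && nzchar(call$ins_seq))
    } else {
      expect_true(call$mh_len == 0L && call$ins_seq == "")
    }
    expect_equal(call$ambiguity_window, call$mh_len + 1L)
  }
})

test_that("rebuilding the fusion from a call reproduces it exactly", {
  set.seed(99)
  for (i in 1:150) {
    mech <- sample(c("blunt", "microhomology", "insertion"), 1)
    inst <- make_junction_instance(mech, h = sample(1:8, 1),
                                   ins = random_dna_str(sample(1:5, 1)))
    call <- classify_junction(inst$fusion, inst$refA, inst$refB)
    rebuilt <- paste0(
      substr(inst$refA, call$startA + 1, call$canonical_posA + 1),
      call$ins_seq,
      substr(inst$refB, call$canonical_posB + 1, call$endB)
    )
    expect_equal(rebuilt, inst$fusion)
  }
})

test_that("leftmost canonicalization is stable under anchor jitter", {
  set.seed(21)
  inst <- make_junction_instance("microhomology", h = 6)
  ref_call <- classify_junction(inst$fusion, inst$refA, inst$refB)
  for (shift in -6:6) {
    call <- classify_junction(inst$fusion, inst$refA, inst$refB,
                              anchorA = inst$i22 + shift,
                              anchorB = inst$i9 + shift)
    expect_equal(call$canonical_posA, ref_call$canonical_posA)
    expect_equal(call$canonical_posB, ref_call$canonical_posB)
    expect_equal(call$mh_len, ref_call$mh_len)
  }
})

test_that("junctions without a sufficient anchor are rejected, not guessed", {
  set.seed(31)
  inst <- make_junction_instance("blunt")
  garbage <- paste0(random_dna_str(40), substr(inst$fusion, 41, 80))
  expect_error(classify_junction(garbage, inst$refA, inst$refB),
               class = "unanchored_junction")
  expect_error(classify_junction("ACGTACGT", inst$refA, inst$refB),
               class = "unanchored_junction")
})

test_that("cohort classification summarizes per-mechanism lengths only", {
  sim <- sim_world(n = 40, seed = 17, mech_probs = c(1, 0, 0))
  res <- classify_cohort(sim$cohort, sim$refA, sim$refB)
  expect_equal(unname(res$fractions), c(1, 0, 0))
  expect_equal(res$mh_summary$n, 40L)
  expect_equal(res$ins_summary$n, 0L)
  expect_true(is.na(res$ins_summary$median))
  expect_equal(res$mh_summary$median,
               stats::median(sim$truth$mh_len))

  # a single blunt junction gives fractions (0, 1, 0)
  sim1 <- sim_world(n = 1, seed = 23, mech_probs = c(0, 1, 0))
  res1 <- classify_cohort(sim1$cohort, sim1$refA, sim1$refB)
  expect_equal(unname(res1$fractions), c(0, 1, 0))

  # unclassifiable records are counted and listed, not dropped
  coh <- sim$cohort
  coh$junction_seq[1] <- random_dna_str(80)
  res2 <- classify_cohort(coh, sim$refA, sim$refB)
  expect_equal(res2$n_classifiable, 39L)
  expect_equal(res2$unclassifiable$patient_id, coh$patient_id[1])
  expect_equal(sum(res2$fractions), 1)
})
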