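# Reciprocal balance arithmetic and cohort concordance counting.

test_that("adjacency on both chromosomes is the perfectly balanced case", {
  s <- reciprocal_deltas(breakpoint_pair(1000, 5000, "forward"),
                         breakpoint_pair(1001, 4999, "reciprocal"))
  expect_equal(s$delta22, 0)
  expect_equal(s$delta9, 0)
  expect_equal(s$class22, "balanced")
  expect_equal(s$class9, "balanced")
  expect_true(s$within_1bp && s$within_100bp_22 && s$within_100bp_9)
})

test_that("a 501-base gap is a 500-base deletion, as set arithmetic confirms", {
  fwd <- breakpoint_pair(1000, 5000, "forward")
  rec <- breakpoint_pair(1501, 4999, "reciprocal")
  s <- reciprocal_deltas(fwd, rec)
  expect_equal(s$delta22, 500)
  expect_equal(s$class22, "deletion")
  orc <- oracle_deltas(1000, 5000, 1501, 4999, len = 6000)
  expect_equal(s$delta22, unname(orc["delta22"]))
  expect_equal(s$delta9, unname(orc["delta9"]))
})

test_that("closed-form deltas equal the set-arithmetic oracle on random pairs", {
  set.seed(404)
  len <- 400
  for (i in 1:2000) {
    p22f <- sample(50:349, 1)
    p9f <- sample(50:349, 1)
    p22r <- sample(50:349, 1)
    p9r <- sample(50:349, 1)
    s <- reciprocal_deltas(breakpoint_pair(p22f, p9f, "forward"),
                           breakpoint_pair(p22r, p9r, "reciprocal"))
    orc <- oracle_deltas(p22f, p9f, p22r, p9r, len)
    expect_equal(s$delta22, unname(orc["delta22"]))
    expect_equal(s$delta9, unname(orc["delta9"]))
    expect_equal(s$class22,
                 if (orc["delta22"] == 0) "balanced"
                 else if (orc["delta22"] > 0) "deletion" else "duplication")
  }
})

test_that("exchanging fusion roles (with junction-base renaming) negates deltas", {
  set.seed(405)
  for (i in 1:200) {
    p22f <- sample(100:1000, 1); p9f <- sample(100:1000, 1)
    p22r <- sample(100:1000, 1); p9r <- sample(100:1000, 1)
    s <- reciprocal_deltas(breakpoint_pair(p22f, p9f, "forward"),
                           breakpoint_pair(p22r, p9r, "reciprocal"))
    # viewing the reciprocal product as "forward": its first-retained
    # chr22 base p22r becomes the new last-retained base p22r - 1, etc.
    s2 <- reciprocal_deltas(breakpoint_pair(p22r - 1, p9r + 1, "forward"),
                            breakpoint_pair(p22f + 1, p9f - 1, "reciprocal"))
    expect_equal(s2$delta22, -s$delta22)
    expect_equal(s2$delta9, -s$delta9)
  }
})

test_that("swapped kinds and missing reciprocals are handled explicitly", {
  fwd <- breakpoint_pair(10, 20, "forward")
  rec <- breakpoint_pair(11, 19, "reciprocal")
  expect_error(reciprocal_deltas(rec, fwd), "forward and a reciprocal")
  s <- reciprocal_deltas(fwd, NULL)
  expect_false(s$available)
})

test_that("cohort concordance counts match a directly constructed truth", {
  # build a cohort with known deltas: 4 balanced, 3 within +/-1, 2 with
  # +/-100 windows broken on one gene, 1 large deletion, 1 large dup
  d22 <- c(0, 0, 0, 0, 1, -1, 1, 60, 200, 15000, 0)
  d9 <- c(0, 0, 0, 0, 0, 1, -1, -200, 50, 0, -12000)
  n <- length(d22)
  pos22 <- rep(5000, n); pos9 <- rep(9000, n)
  coh <- data.frame(pos22 = pos22, pos9 = pos9,
                    pos22_rec = pos22 + 1 + d22,
                    pos9_rec = pos9 - 1 - d9)
  rep_ <- cohort_reciprocal_report(coh)
  expect_equal(rep_$n_paired, n)
  expect_equal(rep_$n_perfectly_balanced, 4L)
  expect_equal(rep_$n_within_1bp_both, 7L)
  expect_equal(rep_$n_within_100bp_22, sum(abs(d22) <= 100))
  expect_equal(rep_$n_within_100bp_9, sum(abs(d9) <= 100))
  expect_equal(rep_$n_del_gt_thresh_22, 1L)
  expect_equal(rep_$n_dup_gt_thresh_9, 1L)
  expect_equal(rep_$max_del_22, 15000)
  expect_equal(rep_$max_dup_9, 12000)
  # threshold monotonicity: large-event counts never grow with the cutoff
  counts <- vapply(c(100, 1000, 10000, 20000), function(thr) {
    r <- cohort_reciprocal_report(coh, large_threshold = thr)
    r$n_del_gt_thresh_22 + r$n_del_gt_thresh_9 +
      r$n_dup_gt_thresh_22 + r$n_dup_gt_thresh_9
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # missing reciprocals are excluded from the denominator
  coh$pos22_rec[1] <- NA
  expect_equal(cohort_reciprocal_report(coh)$n_paired, n - 1L)
  expect_error(cohort_reciprocal_report(coh[1, ]), "no patient")
})

test_that("simulated cohorts conserve drawn imbalances end to end", {
  sim <- sim_world(n = 80, seed = 61)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    s <- reciprocal_deltas(
      breakpoint_pair(tr$pos22[i], tr$pos9[i], "forward"),
      breakpoint_pair(tr$pos22_rec[i], tr$pos9_rec[i], "reciprocal"))
    expect_equal(s$delta22, tr$delta22[i])
    expect_equal(s$delta9, tr$delta9[i])
  }
  rep_ <- cohort_reciprocal_report(sim$cohort)
  expect_equal(rep_$n_paired, 80L)
  expect_equal(rep_$n_perfectly_balanced,
               sum(tr$delta22 == 0 & tr$delta9 == 0))
})
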