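test_that("fold change divides by the floored reference mean", {
  expect_equal(fold_change(10, 40), 4.0)
  expect_equal(fold_change(0, 50), 5000)   # floor 0.01 engages
  expect_equal(fold_change(2, 1, floor = 5), 0.2)
  expect_error(fold_change(-1, 3), "non-negative")
  expect_error(fold_change(1, 3, floor = 0), "floor")
  # published NAAT row: printed FC derives from unrounded FPKM, so the
  # recomputed value agrees within 5%
  fc <- fold_change(0.7, 246.9)
  expect_equal(fc, 352.71428571)
  expect_lt(abs(fc - 356.6) / 356.6, 0.05)
})

test_that("the Welch test matches the hand-derived example and its conventions", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  shifted <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(shifted$t_stat), 3.6742346, tolerance = 1e-6)
  expect_equal(shifted$df, 4)
  expect_gt(shifted$t_stat, 0)  # sign convention: mean(b) - mean(a)

  flat <- welch_t_test(c(0, 0, 0), c(0, 0, 0))
  expect_equal(flat$p_value, 1)
  degenerate <- welch_t_test(c(2, 2, 2), c(5, 5, 5))
  expect_equal(degenerate$p_value, 0)
  expect_equal(degenerate$t_stat, Inf)

  expect_error(welch_t_test(c(1), c(1, 2)), "at least 2")
})

test_that("BH adjustment executes the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("BH agrees with the brute-force step-up definition on random vectors", {
  set.seed(101)
  for (i in 1:100) {
    p <- runif(sample(1:15, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("differential calling flags planted induction and respects the abundance filter", {
  blocks <- list(planted_block("induced_L_only", 5, c(6, 630, 6, 6)),
                 planted_block("null_background", 50, c(20, 20, 20, 20), mean_spread = 0.5))
  sim <- generate_dataset(generator_config(blocks = blocks, noise_sigma = 0.05, seed = 31))
  de <- call_differential(sim$expression, ref = c("L", "control"), alt = c("L", "cadmium"))
  planted <- truth_sets(sim$truth, "induced_L_only")
  expect_true(all(de$direction[de$contig_id %in% planted] == "up"))
  expect_true(all(de$is_deg[de$contig_id %in% planted]))
  # nulls stay unflagged
  expect_false(any(de$is_deg[!de$contig_id %in% planted]))
  # q is never below p
  expect_true(all(de$q_value >= de$p_value - 1e-12))

  # 10-fold change but all values under the abundance cut: not a DEG
  low <- make_flat_expression(matrix(c(0.3, 3, 0.3, 0.3), 1), k = 3)
  low$values <- low$values * exp(matrix(rnorm(12, 0, 0.01), 1))
  de_low <- call_differential(low, ref = c("L", "control"), alt = c("L", "cadmium"))
  expect_gt(de_low$fold_change[1], 2)
  expect_lt(de_low$q_value[1], 0.001)
  expect_false(de_low$is_deg[1])
})

test_that("DEG flags are monotone in the q and fold-change thresholds", {
  sim <- generate_dataset(generator_config(blocks = default_blocks(n_null = 100),
                                           noise_sigma = 0.05, seed = 41))
  strict <- call_differential(sim$expression, c("L", "control"), c("L", "cadmium"),
                              q_threshold = 0.001, fc_threshold = 4)
  relaxed_q <- call_differential(sim$expression, c("L", "control"), c("L", "cadmium"),
                                 q_threshold = 0.01, fc_threshold = 4)
  relaxed_fc <- call_differential(sim$expression, c("L", "control"), c("L", "cadmium"),
                                  q_threshold = 0.001, fc_threshold = 2)
  expect_true(all(relaxed_q$is_deg[strict$is_deg]))
  expect_true(all(relaxed_fc$is_deg[strict$is_deg]))
})

test_that("the expressed-gene filter uses a strict condition-mean threshold", {
  panel <- panel_expression_set()  # worked-example panels, 1 sample per condition
  expressed <- expressed_contigs(panel)
  # every exclusive-panel contig clears 5 FPKM in at least one condition
  expect_setequal(expressed, rownames(panel$values))

  boundary <- make_flat_expression(matrix(c(5, 5, 5, 5,
                                            5.01, 5, 5, 5,
                                            0, 0, 0, 0), 3, byrow = TRUE),
                                   k = 1, contig_ids = c("at5", "above", "zero"))
  expect_identical(expressed_contigs(boundary), "above")
  zeros <- make_flat_expression(matrix(0, 4, 4), k = 2)
  expect_length(expressed_contigs(zeros), 0)
})
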