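test_that("genotype-exclusive filters retain the full published panels", {
  s <- condition_summary(panel_expression_set())
  h1 <- exclusive_set(s, "L")
  expect_setequal(h1$members, example_panel("exclusive_L")$contig_id)
  h2 <- exclusive_set(s, "H")
  expect_setequal(h2$members, example_panel("exclusive_H")$contig_id)
  # exclusive sets are disjoint whenever high > low
  expect_length(intersect(h1$members, h2$members), 0)
  expect_error(exclusive_set(s, "L", high = 5, low = 25), "exceed")

  empty <- make_flat_expression(matrix(numeric(0), 0, 4), k = 1)
  expect_length(exclusive_set(condition_summary(empty), "L")$members, 0)
})

test_that("exclusive filters require the threshold in both conditions and are idempotent", {
  base <- matrix(c(30, 30, 1, 1,    # in: constitutive L, silent H
                   30, 10, 1, 1,    # out: loses constitutive expression under Cd
                   30, 30, 1, 6,    # out: H not silent under Cd
                   4, 4, 30, 30),   # H-exclusive, not L
                 4, byrow = TRUE)
  x <- make_flat_expression(base, k = 1, contig_ids = c("in", "noncons", "leaky", "hside"))
  s <- condition_summary(x)
  expect_identical(exclusive_set(s, "L")$members, "in")
  expect_identical(exclusive_set(s, "H")$members, "hside")
  # idempotence: re-filtering the retained rows changes nothing
  again <- exclusive_set(s[s$contig_id %in% "in", ], "L")
  expect_identical(again$members, "in")
})

test_that("baseline-biased filters need both the 5x background and the DEG call", {
  blocks <- list(planted_block("exclusive_L", 4, c(100, 100, 10, 10)),
                 planted_block("housekeeping", 3, c(20, 20, 20, 20)),     # fails 5x background
                 planted_block("null_background", 40, c(100, 100, 95, 95))) # fails FC/significance
  sim <- generate_dataset(generator_config(blocks = blocks, noise_sigma = 0.01, seed = 51))
  h3 <- baseline_biased_set(sim$expression, "L")
  expect_setequal(h3$members, truth_sets(sim$truth, "exclusive_L"))
  h4 <- baseline_biased_set(sim$expression, "H")
  expect_length(h4$members, 0)
  expect_error(baseline_biased_set(sim$expression, "L", background = 0), "> 0")
})

test_that("response sets recover planted per-genotype regulation with direction", {
  blocks <- list(planted_block("induced_both_strongL", 6, c(6, 630, 34, 245)),
                 planted_block("induced_L_only", 5, c(8, 120, 8, 8)),
                 planted_block("repressed_H_only", 4, c(50, 50, 50, 5)),
                 planted_block("null_background", 60, c(20, 20, 20, 20), mean_spread = 0.5))
  sim <- generate_dataset(generator_config(blocks = blocks, noise_sigma = 0.01, seed = 61))
  tr <- function(l) truth_sets(sim$truth, l)
  resp_L <- response_sets(sim$expression, "L")
  resp_H <- response_sets(sim$expression, "H")
  expect_setequal(resp_L$up$members, c(tr("induced_both_strongL"), tr("induced_L_only")))
  expect_length(resp_L$down$members, 0)
  expect_setequal(resp_H$up$members, tr("induced_both_strongL"))
  expect_setequal(resp_H$down$members, tr("repressed_H_only"))

  spec_sets <- specific_response_sets(resp_L$up, resp_H$up, resp_L$down, resp_H$down)
  expect_setequal(spec_sets$only_L_up$members, tr("induced_L_only"))
  expect_length(spec_sets$only_H_up$members, 0)
  expect_setequal(spec_sets$only_H_down$members, tr("repressed_H_only"))
  shared <- shared_response_sets(resp_L$up, resp_H$up, resp_L$down, resp_H$down)
  expect_setequal(shared$shared_up$members, tr("induced_both_strongL"))
  expect_length(shared$shared_down$members, 0)
})

test_that("specific/shared sets obey the partition property on arbitrary inputs", {
  up_L <- contrast_set("up_L", c("a", "b", "c"))
  up_H <- contrast_set("up_H", c("b"))
  down_L <- contrast_set("down_L", character(0))
  down_H <- contrast_set("down_H", c("z"))
  sp <- specific_response_sets(up_L, up_H, down_L, down_H)
  sh <- shared_response_sets(up_L, up_H, down_L, down_H)
  expect_setequal(sp$only_L_up$members, c("a", "c"))
  expect_setequal(sh$shared_up$members, "b")
  expect_identical(sp$only_H_down$members, "z")

  pieces <- list(sp$only_L_up$members, sp$only_H_up$members, sh$shared_up$members)
  expect_setequal(unlist(pieces), union(up_L$members, up_H$members))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_length(intersect(pieces[[i]], pieces[[j]]), 0)
  }

  # disjoint inputs pass through unchanged
  sp2 <- specific_response_sets(up_L, contrast_set("up_H", "q"), down_L, down_H)
  expect_setequal(sp2$only_L_up$members, up_L$members)
})

test_that("the strong-asymmetry subset applies the fold-change ratio rule", {
  shared <- contrast_set("shared_up", c("nas", "even", "mid"))
  fc_L <- c(nas = 160, even = 12, mid = 50)
  fc_H <- c(nas = 9, even = 12, mid = 10)
  strong <- strong_subset(shared, fc_L, fc_H)
  expect_identical(strong$members, "nas")      # 160/9 ~ 17.8 >= 10
  expect_false("even" %in% strong$members)     # equal fold changes excluded
  expect_error(strong_subset(shared, fc_L, fc_H, ratio_threshold = 1), "> 1")
  expect_error(strong_subset(shared, fc_L[-1], fc_H), "missing")
  # idempotence
  again <- strong_subset(contrast_set(strong$id, strong$members), fc_L, fc_H)
  expect_identical(again$members, strong$members)
})

test_that("subset profiles average the published panel columns", {
  nas <- example_panel("nas")
  x <- panel_expression_set(c("nas", "naat_dmas"))
  s <- condition_summary(x)
  fc <- list(
    fc_L = c(setNames(nas$fc_L, nas$contig_id),
             setNames(example_panel("naat_dmas")$fc_L, example_panel("naat_dmas")$contig_id)),
    fc_H = c(setNames(nas$fc_H, nas$contig_id),
             setNames(example_panel("naat_dmas")$fc_H, example_panel("naat_dmas")$contig_id)))
  prof <- subset_profile(nas$contig_id, s, fc$fc_L, fc$fc_H)
  expect_equal(round(prof$mean_ctrl_L, 1), 6.3)
  expect_equal(round(prof$mean_cd_L, 1), 632.1)
  expect_equal(round(prof$mean_fc_L, 1), 161.5)
  expect_equal(round(prof$mean_ctrl_H, 1), 34.4)
  expect_equal(round(prof$mean_cd_H, 1), 245.0)
  expect_equal(round(prof$mean_fc_H, 1), 8.7)

  single <- subset_profile("contig26634", s, fc$fc_L, fc$fc_H)
  expect_equal(single$mean_fc_L, 77.1)
  expect_equal(single$mean_cd_H, 240.7)

  expect_error(subset_profile(c("contig26634", "ghost"), s, fc$fc_L, fc$fc_H), "ghost")
})

test_that("annotation-matched shared regulators honour the term patterns", {
  shared <- contrast_set("shared_up", c("c1", "c2", "c3"))
  ann <- data.frame(contig_id = c("c1", "c2"),
                    description = c("bHLH38 transcription factor", "peroxidase"),
                    agi_code = NA, terms = c("transcription", NA),
                    stringsAsFactors = FALSE)
  h8 <- matched_regulator_set(shared, ann)
  expect_identical(h8$members, "c1")
  none <- matched_regulator_set(shared, ann, patterns = "aquaporin")
  expect_length(none$members, 0)
})
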