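test_that("simulation is bit-identical under a fixed seed", {
  cfg <- quick_config(seed = 7, n_pbmc = 60, size = 160)
  spiked <- tibble::tibble(aldh1_level = "high", twist_loc = "nuc")
  a <- simulate_cytospin(cfg, spiked)
  b <- simulate_cytospin(cfg, spiked)
  expect_identical(a$image, b$image)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("pure-PBMC images contain no CK-positive ground truth", {
  cs <- simulate_cytospin(quick_config(seed = 3, n_pbmc = 80, size = 192))
  gt <- cs$ground_truth
  expect_equal(nrow(gt), 80)
  expect_true(all(!gt$ck_positive))
  expect_true(all(gt$cell_kind == "pbmc"))
  # CK channel is pure noise: nothing close to the rendered CK intensity
  expect_lt(max(channel(cs, "ck")), 0.3)
  # PBMC marker background is non-zero (ALDH1/TWIST detectable among PBMCs)
  expect_gt(mean(channel(cs, "aldh1")), mean(channel(cs, "ck")))
})

test_that("ground truth is conserved and streams are per-cell stable", {
  spiked <- tibble::tibble(aldh1_level = c("high", "low", "neg"),
                           twist_loc = c("nuc", "cyt", "neg"))
  cfg <- quick_config(seed = 5, n_pbmc = 40, size = 192)
  cs <- simulate_cytospin(cfg, spiked)
  gt <- cs$ground_truth
  expect_equal(sum(gt$cell_kind == "tumour"), nrow(spiked))
  expect_equal(gt$true_aldh1_level[gt$cell_kind == "tumour"],
               spiked$aldh1_level)
  expect_equal(gt$true_twist_loc[gt$cell_kind == "tumour"],
               spiked$twist_loc)
  expect_true(all(gt$ck_positive == (gt$cell_kind == "tumour")))

  # dropping a spiked cell does not reshuffle the PBMC lawn: per-cell
  # attribute streams are untouched, and only the handful of PBMCs whose
  # placement had to avoid the removed cell may relocate
  cs1 <- simulate_cytospin(cfg, spiked[1:2, ])
  p0 <- gt[gt$cell_kind == "pbmc", c("row", "col", "diameter")]
  p1 <- cs1$ground_truth[cs1$ground_truth$cell_kind == "pbmc",
                         c("row", "col", "diameter")]
  expect_equal(p0$diameter, p1$diameter)
  same_pos <- p0$row == p1$row & p0$col == p1$col
  expect_gte(mean(same_pos), 0.9)
})

test_that("simulator rejects invalid configurations", {
  expect_error(sim_config(image_size = c(0, 128)), "positive")
  expect_error(sim_config(tumour_cell_diameter = c(mean = 6, sd = 1)),
               "exceed")
  expect_error(sim_config(pbmc_nucleus_diameter = c(mean = 8, sd = -1)),
               "sds")
  expect_error(
    simulate_cytospin(quick_config(1),
                      tibble::tibble(aldh1_level = "ultra",
                                     twist_loc = "nuc")),
    "aldh1_level")
  # two spiked cells forced onto the same spot exceed the packing limit
  expect_error(
    simulate_cytospin(
      quick_config(1, n_pbmc = 0, size = 128),
      tibble::tibble(aldh1_level = c("high", "high"),
                     twist_loc = c("nuc", "nuc"),
                     row = c(64, 64), col = c(64, 66))),
    "overlap")
  # overcrowding the lawn hits the rejection-sampling packing limit
  expect_error(
    simulate_cytospin(sim_config(n_pbmc = 600, image_size = c(96, 96))),
    "packing limit")
})

test_that("spike-in recovery follows the stage-retention product rule", {
  # all stages perfect: recovery is always 100%
  perfect <- simulate_spike_in(100, c(1, 1), n_replicates = 3, seed = 1)
  expect_true(all(perfect$recovery_pct == 100))

  # single 50% stage at large n: binomial closed form, within 3 sd
  one <- simulate_spike_in(10000, 0.5, n_replicates = 1, seed = 2)
  sd3 <- 3 * sqrt(0.5 * 0.5 / one$n_spiked) * 100
  expect_lt(abs(one$recovery_pct - 50), sd3)

  # two 90% stages compose multiplicatively to 81%
  two <- simulate_spike_in(20000, c(0.9, 0.9), n_replicates = 5, seed = 3)
  expect_lt(abs(mean(two$recovery_pct) - 81), 1)

  expect_error(simulate_spike_in(10, numeric(0)), "at least one stage")
  expect_error(simulate_spike_in(10, c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(simulate_spike_in(0, 0.5), "> 0")
})

test_that("cohort generator respects detection rate and phenotype split", {
  none <- simulate_cohort("early", n_patients = 40, detection_rate = 0,
                          seed = 1)
  expect_true(all(none$total_ctc == 0))

  pure <- simulate_cohort("early", n_patients = 30, detection_rate = 1,
                          phenotype_probs = c(1, 0, 0, 0), seed = 2)
  expect_true(all(pure$total_ctc >= 1))
  expect_equal(pure$n_high_nuc, pure$total_ctc)
  expect_true(all(pure$n_high_cytneg + pure$n_lowneg_nuc +
                    pure$n_lowneg_cytneg == 0))

  # law of large numbers: pooled fractions approach the generating probs
  probs <- c(0.6, 0.2, 0.1, 0.1)
  big <- simulate_cohort("metastatic", n_patients = 10000,
                         detection_rate = 0.5, phenotype_probs = probs,
                         seed = 3)
  pooled <- colSums(big[paste0("n_", c("high_nuc", "high_cytneg",
                                       "lowneg_nuc", "lowneg_cytneg"))])
  expect_lt(max(abs(pooled / sum(pooled) - probs)), 0.01)

  expect_error(simulate_cohort("early", 10, phenotype_probs = c(1, 1, 0, 0)),
               "summing to 1")
  expect_error(simulate_cohort("early", 10, detection_rate = 2), "\\[0, 1\\]")
})

test_that("control-cell sets span their ranges with exact medians", {
  for (s in c(1, 19, 202)) {
    ctrl <- simulate_control_cells(n_per_class = 101, seed = s)
    by <- split(ctrl$exposure, ctrl$level)
    expect_equal(range(by$high), c(5, 25))
    expect_equal(range(by$low), c(30, 55))
    expect_equal(range(by$neg), c(60, 90))
    expect_equal(median(by$high), 15)
    expect_equal(median(by$low), 45)
    expect_equal(median(by$neg), 70)
  }
})
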