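test_that("phenotype assignment collapses marker calls as specified", {
  expect_equal(assign_phenotype("high", "nuc"), "high_nuc")
  expect_equal(assign_phenotype("high", "cyt"), "high_cytneg")
  expect_equal(assign_phenotype("high", "neg"), "high_cytneg")
  expect_equal(assign_phenotype("low", "nuc"), "lowneg_nuc")
  expect_equal(assign_phenotype("neg", "nuc"), "lowneg_nuc")
  expect_equal(assign_phenotype("low", "neg"), "lowneg_cytneg")
  expect_equal(assign_phenotype("neg", "cyt"), "lowneg_cytneg")
  expect_error(assign_phenotype("medium", "nuc"), "aldh1_level")
})

test_that("per-patient percentages match the printed index patients", {
  t4 <- table4_counts()
  ph <- c("high_nuc", "high_cytneg", "lowneg_nuc", "lowneg_cytneg")
  mk <- function(cnt) tibble::tibble(phenotype = rep(ph, cnt))

  expect_equal(summarize_patient(mk(t4$metastatic$p5))$pct,
               c(23.8, 66.7, 0, 9.5))
  expect_equal(summarize_patient(mk(t4$early$p1))$pct, c(0, 0, 0, 100))
  expect_equal(summarize_patient(mk(t4$metastatic$p2))$pct,
               c(90.9, 9.1, 0, 0))
  expect_equal(summarize_patient(mk(t4$early$p4))$pct,
               c(50, 16.7, 33.3, 0))

  expect_error(summarize_patient(tibble::tibble(phenotype = character())),
               "zero CTCs")
})

test_that("summarize_patient derives phenotypes from marker calls", {
  calls <- tibble::tibble(aldh1_level = c("high", "low", "neg"),
                          twist_loc = c("nuc", "cyt", "nuc"))
  s <- summarize_patient(calls)
  # high/nuc -> high_nuc; low/cyt -> lowneg_cytneg; neg/nuc -> lowneg_nuc
  expect_equal(s$n, c(1L, 0L, 1L, 1L))
  expect_equal(attr(s, "total_ctc"), 3L)
})

test_that("cohort summary reproduces the reported detection rates", {
  # 13 of 80 early patients with detectable CTCs
  counts <- matrix(0L, 80, 4)
  counts[1:13, 4] <- 1L
  early <- summarize_cohort(patient_profiles(counts, "early"))
  expect_equal(glance(early)$detection_rate_pct, 16.3)
  # 25 of 50 metastatic patients
  counts2 <- matrix(0L, 50, 4)
  counts2[1:25, 1] <- 2L
  met <- summarize_cohort(patient_profiles(counts2, "metastatic"))
  expect_equal(glance(met)$detection_rate_pct, 50)
})

test_that("cohort summary statistics hold their internal invariants", {
  prof <- simulate_cohort("metastatic", 60, seed = 5)
  s <- summarize_cohort(prof)
  tab <- tidy(s)
  ph <- tab[tab$category %in% c("high_nuc", "high_cytneg", "lowneg_nuc",
                                "lowneg_cytneg"), ]
  # the four phenotype CTC-level percentages partition the pooled CTCs
  expect_equal(sum(ph$ctc_pct), 100, tolerance = 1e-9)
  # exclusive is a subset of with-any, per category
  expect_true(all(tab$patients_exclusive_pct <= tab$patients_with_any_pct))
  # counts are conserved from patients to pooled totals
  det <- prof[prof$total_ctc >= 1, ]
  expect_equal(sum(ph$ctc_n), sum(det$total_ctc))
  expect_equal(glance(s)$total_ctc, sum(det$total_ctc))
  # marker margins also partition the pool
  expect_equal(tab$ctc_pct[tab$category == "aldh1_high"] +
                 tab$ctc_pct[tab$category == "aldh1_lowneg"], 100)
})

test_that("a uniform cohort reports 100% everywhere for its phenotype", {
  counts <- matrix(0L, 10, 4)
  counts[, 1] <- 3L
  s <- summarize_cohort(patient_profiles(counts, "early"))
  row <- tidy(s)[tidy(s)$category == "high_nuc", ]
  expect_equal(row$patients_with_any_pct, 100)
  expect_equal(row$patients_exclusive_pct, 100)
  expect_equal(row$ctc_pct, 100)
  expect_equal(row$per_patient_mean_pct, 100)
})

test_that("profile validation catches malformed tables", {
  bad <- patient_profiles(matrix(1L, 3, 4))
  bad$total_ctc[1] <- 99L
  expect_error(summarize_cohort(bad), "total_ctc")
  expect_error(patient_profiles(matrix(-1L, 2, 4)), "non-negative")
})

test_that("generated cohorts recover their phenotype probabilities", {
  probs <- c(0.615, 0.22, 0.088, 0.077)
  prof <- simulate_cohort("metastatic", 4000, detection_rate = 0.5,
                          phenotype_probs = probs, seed = 11)
  s <- tidy(summarize_cohort(prof))
  pooled_n <- sum(prof$total_ctc)
  ph <- s[s$category %in% c("high_nuc", "high_cytneg", "lowneg_nuc",
                            "lowneg_cytneg"), ]
  # each pooled fraction within the binomial 95% CI of its probability
  for (i in 1:4) {
    half <- 1.96 * sqrt(probs[i] * (1 - probs[i]) / pooled_n)
    expect_lt(abs(ph$ctc_pct[i] / 100 - probs[i]), half + 1e-9)
  }
})
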