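test_that("Yates chi-square matches the printed cohort contrasts", {
  # patients with any ALDH1-high CTC: 4/13 early vs 20/25 metastatic
  p_any <- chi_square_yates(rbind(c(4, 9), c(20, 5)))$p.value
  expect_equal(round(p_any, 3), 0.009)
  # exclusively ALDH1-high: 2/13 vs 17/25
  p_excl <- chi_square_yates(rbind(c(2, 11), c(17, 8)))$p.value
  expect_equal(round(p_excl, 3), 0.006)
  # a perfectly balanced table carries no association
  flat <- chi_square_yates(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
})

test_that("Yates chi-square agrees with the direct-formula oracle", {
  set.seed(123)
  n_checked <- 0
  while (n_checked < 100) {
    tab <- matrix(rpois(4, lambda = sample(3:25, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ours <- chi_square_yates(tab)
    orc <- yates_oracle(tab)
    expect_equal(ours$statistic, orc$statistic, tolerance = 1e-10)
    expect_equal(ours$p.value, orc$p.value, tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_error(chi_square_yates(rbind(c(0, 0), c(1, 2))), "margins")
  expect_error(chi_square_yates(rbind(c(1.5, 2), c(1, 2))), "integers")
})

test_that("Mann-Whitney handles the textbook cases", {
  # complete separation of 3 vs 3: U = 0, exact two-sided p = 0.1
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p.value, 0.1)
  expect_equal(res$method, "exact")

  # identical samples: no evidence of a shift
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p.value, 0.99)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney agrees with full-enumeration oracle for small n", {
  set.seed(31)
  for (i in 1:100) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- round(runif(n1, 0, 100), 6)   # continuous: ties impossible
    b <- round(runif(n2, 0, 100), 6)
    ours <- mann_whitney(a, b)
    expect_equal(ours$p.value, mw_exact_oracle(a, b), tolerance = 1e-12)
    expect_equal(ours$u, sum(outer(a, b, ">")))
  }
})

test_that("tied samples fall back to the corrected normal approximation", {
  a <- c(10, 10, 20, 30); b <- c(10, 20, 20, 40)
  res <- mann_whitney(a, b)
  expect_match(res$method, "tie-corrected")
  expect_true(res$p.value > 0 && res$p.value <= 1)
})

test_that("Spearman correlation behaves at the extremes and under the null", {
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, 1 - x)$rho, -1)

  flagged <- spearman_rho(rep(1, 10), rbinom(10, 1, 0.5))
  expect_true(is.na(flagged$rho))
  expect_match(flagged$note, "constant")

  set.seed(5)
  rhos <- replicate(200, spearman_rho(rbinom(60, 1, 0.5),
                                      rbinom(60, 1, 0.5))$rho)
  expect_lt(abs(mean(rhos)), 0.05)  # centred on zero under independence
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("cohort comparison reproduces the table layout and edge cases", {
  t4 <- table4_counts()
  early <- patient_profiles(do.call(rbind, t4$early), "early")
  met <- patient_profiles(do.call(rbind, t4$metastatic), "metastatic")
  cmp <- compare_cohorts(early, met)
  tab <- tidy(cmp)
  expect_equal(nrow(tab), 8)
  expect_true(all(c("p_with_any", "p_exclusive", "p_per_patient")
                  %in% names(tab)))
  # identical cohorts: every computable contrast is null
  cmp0 <- compare_cohorts(early, early)
  p0 <- tidy(cmp0)$p_per_patient
  expect_true(all(p0[!is.na(p0)] > 0.99))
  expect_true(all(tidy(cmp0)$early_with_any_pct ==
                    tidy(cmp0)$metastatic_with_any_pct))

  g <- glance(cmp)
  expect_equal(g$early_detected, 5L)
  expect_equal(g$metastatic_detected, 7L)

  bh <- compare_cohorts(early, met, bh = TRUE)
  expect_true(all(tidy(bh)$p_with_any_bh >= tidy(bh)$p_with_any,
                  na.rm = TRUE))
})

test_that("distinct generating phenotype mixes are usually detected", {
  # power check: 13 vs 25 patients, strongly different high_nuc prevalence
  hits <- 0
  for (s in 1:20) {
    e <- simulate_cohort("early", 13, detection_rate = 1,
                         phenotype_probs = c(0.13, 0.26, 0.19, 0.42),
                         seed = 400 + s)
    m <- simulate_cohort("metastatic", 25, detection_rate = 1,
                         phenotype_probs = c(0.76, 0.12, 0.06, 0.06),
                         seed = 800 + s)
    p <- tidy(compare_cohorts(e, m))
    p_hn <- p$p_with_any[p$category == "high_nuc"]
    if (!is.na(p_hn) && p_hn < 0.05) hits <- hits + 1
  }
  expect_gt(hits, 10)  # rejects in the majority of replicates
})

test_that("pooled marker indicators correlate as built", {
  # every CTC high_nuc or lowneg_cytneg: indicators perfectly concordant
  counts <- matrix(0L, 6, 4)
  counts[1:3, 1] <- 4L
  counts[4:6, 4] <- 4L
  cmp <- compare_cohorts(patient_profiles(counts, "early"),
                         patient_profiles(counts, "metastatic"))
  expect_equal(cmp$correlation$rho, c(1, 1))
})
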