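#' Chi-square test with continuity correction on a 2 x 2 table
#'
#' The Yates-corrected chi-square statistic
#' `sum((max(0, |O - E| - 0.5))^2 / E)` with expected counts from the table
#' margins, referred to the chi-square distribution with 1 degree of
#' freedom. All margins must be positive.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
#' @examples
#' chi_square_yates(matrix(c(4, 9, 20, 5), 2, byrow = TRUE))
chi_square_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2 x 2")
  if (any(table < 0) || any(table != round(table))) {
    abort("table entries must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all table margins must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  tibble(statistic = unname(ht$statistic), df = 1L,
         p.value = unname(ht$p.value),
         method = "chi-square with continuity correction")
}

#' Mann-Whitney U test (two-sided)
#'
#' Compares two samples of per-patient percentages (or any ordinal data).
#' Small untied samples use the exact U distribution; otherwise the normal
#' approximation with tie correction and continuity correction is used. The
#' method actually applied is recorded in the output.
#'
#' @param a,b Non-empty numeric vectors.
#' @return One-row tibble: `u`, `p.value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) < 50 && length(b) < 50
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  tibble(u = unname(ht$statistic), p.value = unname(ht$p.value),
         method = if (exact) "exact" else "normal approximation (tie-corrected)")
}

#' Spearman rank correlation (two-sided)
#'
#' Rank correlation with midranks for ties, as used to test the association
#' of marker indicators across pooled single CTCs. A constant input vector
#' leaves the correlation undefined; this is flagged rather than an error.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return One-row tibble: `rho`, `p.value`, `method`, `note`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(tibble(rho = NA_real_, p.value = NA_real_,
                  method = "Spearman rank correlation",
                  note = "undefined: constant input vector"))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  tibble(rho = unname(ht$estimate), p.value = unname(ht$p.value),
         method = "Spearman rank correlation", note = NA_character_)
}

#' Compare CTC phenotype frequencies between two cohorts
#'
#' Reproduces the row layout of the cohort comparison tables: for every
#' category (single-marker classes and the four co-expression phenotypes),
#' a Yates-corrected chi-square test on the 2 x 2 table of patients with
#' any CTC of the category (and on the exclusively-that-category table),
#' and a Mann-Whitney test on the per-patient CTC percentage distributions.
#' Only patients with detectable CTCs enter, following the source
#' reporting convention (configurable). Within each cohort the Spearman
#' correlations between the ALDH1-high and TWIST-nuclear indicators of
#' pooled single CTCs are also reported.
#'
#' @param early,metastatic Patient-profile tibbles (see
#'   [patient_profiles()], [simulate_cohort()]).
#' @param include_negative If `TRUE`, CTC-negative patients enter the
#'   Mann-Whitney samples as zeros (default `FALSE`: detected only).
#' @param bh If `TRUE`, append Benjamini-Hochberg adjusted p-values (no
#'   multiplicity correction is applied by default).
#' @return An object of class `ctc_cohort_comparison`: list with
#'   `comparison` (tibble, one row per category), `correlation` (Spearman
#'   results per cohort), and the two `ctc_cohort` summaries.
#' @export
compare_cohorts <- function(early, metastatic, include_negative = FALSE,
                            bh = FALSE) {
  sum_e <- summarize_cohort(early)
  sum_m <- summarize_cohort(metastatic)
  det_e <- sum_e$profiles[sum_e$profiles$total_ctc >= 1, , drop = FALSE]
  det_m <- sum_m$profiles[sum_m$profiles$total_ctc >= 1, , drop = FALSE]
  if (!nrow(det_e) || !nrow(det_m)) {
    abort("both cohorts need at least one detected patient")
  }
  cnt_e <- category_counts(det_e)
  cnt_m <- category_counts(det_m)
  pct_base_e <- if (include_negative) category_counts(sum_e$profiles) else cnt_e
  tot_e <- if (include_negative) sum_e$profiles$total_ctc else det_e$total_ctc
  pct_base_m <- if (include_negative) category_counts(sum_m$profiles) else cnt_m
  tot_m <- if (include_negative) sum_m$profiles$total_ctc else det_m$total_ctc

  rows <- purrr::map(CATEGORY_LEVELS, function(cat) {
    any_tab <- rbind(c(sum(cnt_e[, cat] >= 1), sum(cnt_e[, cat] == 0)),
                     c(sum(cnt_m[, cat] >= 1), sum(cnt_m[, cat] == 0)))
    excl_tab <- rbind(
      c(sum(cnt_e[, cat] == det_e$total_ctc),
        sum(cnt_e[, cat] != det_e$total_ctc)),
      c(sum(cnt_m[, cat] == det_m$total_ctc),
        sum(cnt_m[, cat] != det_m$total_ctc)))
    p_any <- safe_yates(any_tab)
    p_excl <- safe_yates(excl_tab)
    mw <- mann_whitney(100 * pct_base_e[, cat] / pmax(tot_e, 1),
                       100 * pct_base_m[, cat] / pmax(tot_m, 1))
    tibble(
      category = cat,
      early_with_any_pct = 100 * mean(cnt_e[, cat] >= 1),
      metastatic_with_any_pct = 100 * mean(cnt_m[, cat] >= 1),
      p_with_any = p_any,
      early_exclusive_pct = 100 * mean(cnt_e[, cat] == det_e$total_ctc),
      metastatic_exclusive_pct = 100 * mean(cnt_m[, cat] == det_m$total_ctc),
      p_exclusive = p_excl,
      early_mean_pct = mean(100 * pct_base_e[, cat] / pmax(tot_e, 1)),
      metastatic_mean_pct = mean(100 * pct_base_m[, cat] / pmax(tot_m, 1)),
      p_per_patient = mw$p.value,
      early_ctc_pct = 100 * sum(cnt_e[, cat]) / sum(det_e$total_ctc),
      metastatic_ctc_pct = 100 * sum(cnt_m[, cat]) / sum(det_m$total_ctc))
  })
  comparison <- bind_rows(rows)
  if (bh) {
    comparison <- comparison |>
      mutate(p_with_any_bh = stats::p.adjust(.data$p_with_any, "BH"),
             p_exclusive_bh = stats::p.adjust(.data$p_exclusive, "BH"),
             p_per_patient_bh = stats::p.adjust(.data$p_per_patient, "BH"))
  }
  correlation <- bind_rows(
    cohort_correlation(det_e, "early"),
    cohort_correlation(det_m, "metastatic"))
  structure(list(comparison = comparison, correlation = correlation,
                 early = sum_e, metastatic = sum_m),
            class = "ctc_cohort_comparison")
}

# Yates chi-square p, NA when a margin is empty (e.g. a category absent
# from both cohorts) rather than an error mid-report.
safe_yates <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  chi_square_yates(tab)$p.value
}

# Spearman correlation between per-CTC binary indicators (ALDH1-high,
# TWIST-nuclear) across the pooled CTCs of one cohort.
cohort_correlation <- function(det, setting) {
  x <- integer(0); y <- integer(0)
  for (i in seq_len(nrow(det))) {
    ph <- rep(PHENOTYPE_LEVELS,
              c(det$n_high_nuc[i], det$n_high_cytneg[i],
                det$n_lowneg_nuc[i], det$n_lowneg_cytneg[i]))
    x <- c(x, as.integer(ph %in% c("high_nuc", "high_cytneg")))
    y <- c(y, as.integer(ph %in% c("high_nuc", "lowneg_nuc")))
  }
  if (length(x) < 3) {
    return(tibble(setting = setting, rho = NA_real_, p.value = NA_real_,
                  method = "Spearman rank correlation",
                  note = "fewer than 3 pooled CTCs"))
  }
  res <- spearman_rho(x, y)
  res$setting <- setting
  res[, c("setting", "rho", "p.value", "method", "note")]
}

#' @export
print.ctc_cohort_comparison <- function(x, digits = 3, ...) {
  cat("Early vs metastatic CTC phenotype comparison\n")
  de <- x$early$detection; dm <- x$metastatic$detection
  cat(sprintf("  early: %d/%d detected (%.1f%%), %d CTCs; metastatic: %d/%d (%.1f%%), %d CTCs\n",
              de$n_detected, de$n_patients, de$detection_rate_pct, de$total_ctc,
              dm$n_detected, dm$n_patients, dm$detection_rate_pct, dm$total_ctc))
  s <- x$comparison |>
    mutate(across(dplyr::where(is.numeric), ~ round(.x, digits)))
  print(as.data.frame(s), row.names = FALSE)
  cat("Pooled per-CTC marker correlation (ALDH1-high vs TWIST-nuclear):\n")
  print(as.data.frame(x$correlation), row.names = FALSE)
  invisible(x)
}
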