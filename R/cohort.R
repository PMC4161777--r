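PHENOTYPE_LEVELS <- c("high_nuc", "high_cytneg", "lowneg_nuc", "lowneg_cytneg")

# Reported percentages use conventional half-up rounding (13/80 -> 16.3%),
# matching clinical-table practice; R's round() would give 16.2.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

CATEGORY_LEVELS <- c("aldh1_high", "aldh1_lowneg", "twist_nuc", "twist_cytneg",
                     PHENOTYPE_LEVELS)

count_cols <- function() paste0("n_", PHENOTYPE_LEVELS)

#' Assign the four-way co-expression phenotype
#'
#' Deterministic mapping from the single-marker calls to the four
#' co-expression phenotypes: ALDH1 `high` stays `high` while `low` and
#' `neg` collapse to `lowneg`; TWIST `nuc` stays `nuc` while `cyt` and
#' `neg` collapse to `cytneg`.
#'
#' @param aldh1_level Character vector in `c("high", "low", "neg")`.
#' @param twist_loc Character vector in `c("nuc", "cyt", "neg")`.
#' @return Character vector in `c("high_nuc", "high_cytneg", "lowneg_nuc",
#'   "lowneg_cytneg")`.
#' @export
#' @examples
#' assign_phenotype(c("high", "neg", "low"), c("nuc", "nuc", "neg"))
assign_phenotype <- function(aldh1_level, twist_loc) {
  if (!all(aldh1_level %in% c("high", "low", "neg"))) {
    abort("aldh1_level values must be high, low or neg")
  }
  if (!all(twist_loc %in% c("nuc", "cyt", "neg"))) {
    abort("twist_loc values must be nuc, cyt or neg")
  }
  a <- ifelse(aldh1_level == "high", "high", "lowneg")
  t <- ifelse(twist_loc == "nuc", "nuc", "cytneg")
  paste(a, t, sep = "_")
}

#' Summarize one patient's CTC phenotype distribution
#'
#' Counts a patient's CTCs by co-expression phenotype and expresses each
#' count as a percentage of that patient's CTCs, rounded to one decimal at
#' reporting time (internal aggregation elsewhere always uses the raw
#' counts). A patient with zero CTCs is CTC-negative and excluded from
#' phenotype reporting, so an empty input is an error.
#'
#' @param calls A data frame of per-CTC calls with either a `phenotype`
#'   column or `aldh1_level` + `twist_loc` columns.
#' @return Tibble with columns `phenotype`, `n`, `pct` (one row per
#'   phenotype, in canonical order), and attribute `total_ctc`.
#' @export
#' @examples
#' summarize_patient(tibble::tibble(
#'   phenotype = rep(c("high_nuc", "high_cytneg"), c(5, 14))))
summarize_patient <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    abort("patient has zero CTCs: CTC-negative patients are excluded from phenotype summaries")
  }
  if (!"phenotype" %in% names(calls)) {
    if (!all(c("aldh1_level", "twist_loc") %in% names(calls))) {
      abort("calls needs a 'phenotype' column or 'aldh1_level' + 'twist_loc'")
    }
    calls$phenotype <- assign_phenotype(calls$aldh1_level, calls$twist_loc)
  }
  if (!all(calls$phenotype %in% PHENOTYPE_LEVELS)) {
    abort("unknown phenotype values")
  }
  n <- vapply(PHENOTYPE_LEVELS, function(p) sum(calls$phenotype == p),
              integer(1))
  out <- tibble(phenotype = PHENOTYPE_LEVELS, n = unname(n),
                pct = round_half_up(100 * unname(n) / nrow(calls), 1))
  attr(out, "total_ctc") <- nrow(calls)
  out
}

#' Build a patient-profile table from phenotype counts
#'
#' Convenience constructor for the tabular patient representation used by
#' the cohort summaries: one row per patient with the four phenotype counts.
#'
#' @param counts Matrix or data frame with four columns (counts of
#'   `high_nuc`, `high_cytneg`, `lowneg_nuc`, `lowneg_cytneg`), one row per
#'   patient.
#' @param setting Cohort label recycled across patients.
#' @param patient_id Optional ids (default `P1..Pn`).
#' @param pbmcs_analyzed Reporting denominator (default 5e5).
#' @return Patient-profile tibble compatible with [summarize_cohort()].
#' @export
patient_profiles <- function(counts, setting = "early", patient_id = NULL,
                             pbmcs_analyzed = 500000L) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4 || any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be a patients x 4 matrix of non-negative integers")
  }
  n <- nrow(counts)
  tibble(
    patient_id = patient_id %||% paste0("P", seq_len(n)),
    setting = rep(setting, length.out = n),
    pbmcs_analyzed = as.integer(pbmcs_analyzed),
    n_high_nuc = as.integer(counts[, 1]),
    n_high_cytneg = as.integer(counts[, 2]),
    n_lowneg_nuc = as.integer(counts[, 3]),
    n_lowneg_cytneg = as.integer(counts[, 4]),
    total_ctc = as.integer(rowSums(counts)))
}

# Per-patient counts for every reporting category (marker margins plus the
# four co-expression phenotypes), as a patients x category matrix.
category_counts <- function(profiles) {
  m <- cbind(
    aldh1_high = profiles$n_high_nuc + profiles$n_high_cytneg,
    aldh1_lowneg = profiles$n_lowneg_nuc + profiles$n_lowneg_cytneg,
    twist_nuc = profiles$n_high_nuc + profiles$n_lowneg_nuc,
    twist_cytneg = profiles$n_high_cytneg + profiles$n_lowneg_cytneg,
    high_nuc = profiles$n_high_nuc, high_cytneg = profiles$n_high_cytneg,
    lowneg_nuc = profiles$n_lowneg_nuc,
    lowneg_cytneg = profiles$n_lowneg_cytneg)
  m[, CATEGORY_LEVELS, drop = FALSE]
}

validate_profiles <- function(profiles) {
  profiles <- as_tibble(profiles)
  need <- c(count_cols(), "total_ctc")
  if (!all(need %in% names(profiles))) {
    abort(sprintf("patient profiles need columns: %s",
                  paste(need, collapse = ", ")))
  }
  cnt <- as.matrix(profiles[count_cols()])
  if (any(cnt < 0)) abort("phenotype counts must be non-negative")
  if (any(rowSums(cnt) != profiles$total_ctc)) {
    abort("total_ctc must equal the sum of the four phenotype counts")
  }
  profiles
}

#' Summarize a patient cohort (the per-category reporting table)
#'
#' Computes, over all patients, the CTC detection rate, and — over detected
#' patients only, as in the source reporting convention — for each category
#' (the two single-marker classes of each marker and the four co-expression
#' phenotypes): the percentage of patients with any CTC of that category,
#' the percentage whose CTCs are exclusively of that category, the
#' unweighted mean (and range) of per-patient CTC percentages, and the
#' category's share of the pooled CTCs.
#'
#' @param profiles Patient-profile tibble (see [patient_profiles()] or
#'   [simulate_cohort()]); patients with `total_ctc = 0` count only toward
#'   the detection rate.
#' @return An object of class `ctc_cohort`: list with `summary` (tibble,
#'   one row per category), `detection` (one-row tibble) and `profiles`.
#' @export
summarize_cohort <- function(profiles) {
  profiles <- validate_profiles(profiles)
  if (nrow(profiles) == 0) abort("at least one patient profile required")
  detected <- profiles$total_ctc >= 1
  det <- profiles[detected, , drop = FALSE]
  detection <- tibble(
    n_patients = nrow(profiles),
    n_detected = sum(detected),
    detection_rate_pct = round_half_up(100 * mean(detected), 1),
    total_ctc = sum(det$total_ctc),
    median_ctc_per_detected = if (nrow(det)) median(det$total_ctc) else NA_real_,
    min_ctc = if (nrow(det)) min(det$total_ctc) else NA_integer_,
    max_ctc = if (nrow(det)) max(det$total_ctc) else NA_integer_)
  if (!nrow(det)) {
    return(structure(list(summary = tibble(), detection = detection,
                          profiles = profiles), class = "ctc_cohort"))
  }
  cat_cnt <- category_counts(det)
  pct <- 100 * sweep(cat_cnt, 1, det$total_ctc, "/")
  summary <- tibble(
    category = CATEGORY_LEVELS,
    patients_with_any_n = unname(colSums(cat_cnt >= 1)),
    patients_with_any_pct = unname(100 * colMeans(cat_cnt >= 1)),
    patients_exclusive_n = unname(colSums(cat_cnt == det$total_ctc)),
    patients_exclusive_pct = unname(100 * colMeans(cat_cnt == det$total_ctc)),
    per_patient_mean_pct = unname(colMeans(pct)),
    per_patient_min_pct = unname(apply(pct, 2, min)),
    per_patient_max_pct = unname(apply(pct, 2, max)),
    ctc_n = unname(colSums(cat_cnt)),
    ctc_pct = unname(100 * colSums(cat_cnt) / sum(det$total_ctc)))
  structure(list(summary = summary, detection = detection,
                 profiles = profiles),
            class = "ctc_cohort")
}

#' @export
print.ctc_cohort <- function(x, digits = 1, ...) {
  d <- x$detection
  cat(sprintf("CTC cohort: %d/%d patients with detectable CTCs (%.1f%%), %d CTCs pooled\n",
              d$n_detected, d$n_patients, d$detection_rate_pct, d$total_ctc))
  if (nrow(x$summary)) {
    s <- x$summary |>
      mutate(across(dplyr::ends_with("_pct"), ~ round(.x, digits)))
    print(as.data.frame(s), row.names = FALSE)
  }
  invisible(x)
}
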