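#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ALDH1 calibration model
#'
#' @param x An [calibration_model()].
#' @param ... Unused.
#' @return Per-class tibble (`level`, `n`, `range_min`, `range_max`,
#'   `median`, `se`) when the model was fitted with [derive_cutoffs()];
#'   otherwise the configured class ranges.
#' @export
tidy.aldh1_calibration <- function(x, ...) {
  if (!is.null(x$class_stats)) return(as_tibble(x$class_stats))
  tibble(level = factor(c("high", "low", "neg"),
                        levels = c("high", "low", "neg")),
         n = NA_integer_,
         range_min = c(x$grid_min, x$low_min, x$neg_min),
         range_max = c(x$high_max, x$low_max, x$grid_max),
         median = NA_real_, se = NA_real_)
}

#' @rdname tidy.aldh1_calibration
#' @return `glance()`: one-row tibble of the cut-offs and map constants.
#' @export
glance.aldh1_calibration <- function(x, ...) {
  tibble(high_max = x$high_max, low_min = x$low_min, low_max = x$low_max,
         neg_min = x$neg_min, grid_min = x$grid_min, grid_max = x$grid_max,
         step = x$step, scale = x$scale)
}

#' Tidy a cohort summary
#'
#' @param x A `ctc_cohort` from [summarize_cohort()].
#' @param ... Unused.
#' @return `tidy()`: the per-category summary tibble. `glance()`: the
#'   one-row detection summary.
#' @export
tidy.ctc_cohort <- function(x, ...) as_tibble(x$summary)

#' @rdname tidy.ctc_cohort
#' @export
glance.ctc_cohort <- function(x, ...) as_tibble(x$detection)

#' Tidy a cohort comparison
#'
#' @param x A `ctc_cohort_comparison` from [compare_cohorts()].
#' @param ... Unused.
#' @return `tidy()`: one row per category with frequencies and p-values.
#'   `glance()`: one row with cohort sizes, detection rates and the pooled
#'   per-CTC marker correlations.
#' @export
tidy.ctc_cohort_comparison <- function(x, ...) as_tibble(x$comparison)

#' @rdname tidy.ctc_cohort_comparison
#' @export
glance.ctc_cohort_comparison <- function(x, ...) {
  de <- x$early$detection; dm <- x$metastatic$detection
  rho_m <- x$correlation[x$correlation$setting == "metastatic", ]
  tibble(
    early_patients = de$n_patients, early_detected = de$n_detected,
    early_detection_pct = de$detection_rate_pct, early_ctc = de$total_ctc,
    metastatic_patients = dm$n_patients, metastatic_detected = dm$n_detected,
    metastatic_detection_pct = dm$detection_rate_pct,
    metastatic_ctc = dm$total_ctc,
    metastatic_rho = rho_m$rho, metastatic_rho_p = rho_m$p.value)
}
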