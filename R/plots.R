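#' Plot a cytospin image as channel facets
#'
#' Renders each fluorescence channel as a raster facet, optionally
#' overlaying ground-truth tumour-cell centres.
#'
#' @param object A `cytospin`.
#' @param show_truth Overlay ground-truth tumour centres (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cytospin <- function(object, show_truth = TRUE, ...) {
  df <- purrr::map(object$channels, function(ch) {
    m <- channel(object, ch)
    tibble(channel = ch,
           row = rep(seq_len(nrow(m)), times = ncol(m)),
           col = rep(seq_len(ncol(m)), each = nrow(m)),
           intensity = as.vector(m))
  }) |> bind_rows() |>
    mutate(channel = factor(.data$channel, levels = object$channels))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  gt <- object$ground_truth
  if (show_truth && !is.null(gt) && any(gt$cell_kind == "tumour")) {
    tum <- gt[gt$cell_kind == "tumour", ]
    p <- p + ggplot2::geom_point(
      data = tum, ggplot2::aes(.data$col, .data$row),
      colour = "red", shape = 1, size = 4, inherit.aes = FALSE)
  }
  p
}

#' Plot a cohort phenotype summary
#'
#' Bar chart of the per-category patient frequencies (any / exclusive) and
#' pooled CTC-level percentages of a cohort summary.
#'
#' @param object A `ctc_cohort` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctc_cohort <- function(object, ...) {
  object$summary |>
    select("category", "patients_with_any_pct", "patients_exclusive_pct",
           "ctc_pct") |>
    tidyr::pivot_longer(-"category", names_to = "measure",
                        values_to = "pct") |>
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS)) |>
    ggplot2::ggplot(ggplot2::aes(.data$category, .data$pct,
                                 fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an early-vs-metastatic comparison
#'
#' Side-by-side patient frequencies per category for the two cohorts,
#' annotated with the chi-square p-values.
#'
#' @param object A `ctc_cohort_comparison` from [compare_cohorts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctc_cohort_comparison <- function(object, ...) {
  df <- object$comparison |>
    select("category", early = "early_with_any_pct",
           metastatic = "metastatic_with_any_pct", "p_with_any") |>
    tidyr::pivot_longer(c("early", "metastatic"), names_to = "setting",
                        values_to = "pct") |>
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS))
  lab <- object$comparison |>
    mutate(category = factor(.data$category, levels = CATEGORY_LEVELS),
           label = ifelse(is.na(.data$p_with_any), "",
                          sprintf("p=%.3f", .data$p_with_any)))
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$pct,
                                   fill = .data$setting)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$category, 102, label = .data$label),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = NULL, y = "patients with any CTC of category (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
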