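#' Classify TWIST subcellular localization per cell
#'
#' TWIST is detected in a compartment when the fraction of its pixels above
#' `detection_threshold` reaches `min_positive_fraction`. The localization
#' call follows the scoring rule of the assay: a cell is `nuc` whenever
#' nuclear TWIST is detected, regardless of any cytoplasmic co-localization;
#' `cyt` when TWIST is exclusively cytoplasmic; `neg` when neither
#' compartment is positive. Cells with an empty cytoplasm mask simply score
#' cytoplasmic-negative (not an error).
#'
#' @param twist H x W numeric matrix (TWIST channel).
#' @param nuclei,cells Label matrices (matching labels).
#' @param detection_threshold Intensity above which a pixel counts as
#'   TWIST-positive. `NULL` (default) estimates background mean + `k` sd
#'   from pixels outside all cells.
#' @param min_positive_fraction Minimum positive-pixel fraction of a
#'   compartment (default 0.3).
#' @param k Background-sd multiplier for the automatic threshold.
#' @return Tibble: `cell_id`, `twist_nuc_frac`, `twist_cyt_frac`,
#'   `twist_nuclear_detected`, `twist_cytoplasmic_detected`, `twist_loc`.
#' @export
classify_twist <- function(twist, nuclei, cells,
                           detection_threshold = NULL,
                           min_positive_fraction = 0.3, k = 5) {
  stopifnot(is.matrix(twist), all(dim(twist) == dim(nuclei)),
            all(dim(twist) == dim(cells)))
  if (min_positive_fraction <= 0 || min_positive_fraction > 1) {
    abort("min_positive_fraction must be in (0, 1]")
  }
  n <- max(cells, nuclei)
  if (n == 0) {
    return(tibble(cell_id = integer(), twist_nuc_frac = numeric(),
                  twist_cyt_frac = numeric(),
                  twist_nuclear_detected = logical(),
                  twist_cytoplasmic_detected = logical(),
                  twist_loc = character()))
  }
  if (is.null(detection_threshold)) {
    bg <- twist[cells == 0]
    if (!length(bg)) bg <- as.vector(twist)
    detection_threshold <- mean(bg) + k * sd(bg)
  }
  pos <- as.vector(twist > detection_threshold)
  cell_v <- as.vector(cells); nuc_v <- as.vector(nuclei)
  in_cell <- cell_v > 0
  lab <- cell_v[in_cell]
  is_nuc <- nuc_v[in_cell] == lab
  nuc_area <- tab_n(lab[is_nuc], n)
  cyt_area <- tab_n(lab[!is_nuc], n)
  nuc_pos <- tab_n(lab[is_nuc & pos[in_cell]], n)
  cyt_pos <- tab_n(lab[!is_nuc & pos[in_cell]], n)
  nuc_frac <- ifelse(nuc_area > 0, nuc_pos / nuc_area, 0)
  cyt_frac <- ifelse(cyt_area > 0, cyt_pos / cyt_area, 0)
  nuc_det <- nuc_frac >= min_positive_fraction
  cyt_det <- cyt_frac >= min_positive_fraction
  tibble(cell_id = seq_len(n),
         twist_nuc_frac = nuc_frac, twist_cyt_frac = cyt_frac,
         twist_nuclear_detected = nuc_det,
         twist_cytoplasmic_detected = cyt_det,
         twist_loc = twist_localization(nuc_det, cyt_det))
}

#' TWIST localization from compartment detections
#'
#' Pure scoring rule: nuclear detection dominates (`nuc` regardless of
#' cytoplasmic co-localization), exclusively-cytoplasmic detection scores
#' `cyt`, otherwise `neg`.
#'
#' @param nuclear_detected,cytoplasmic_detected Logical vectors.
#' @return Character vector in `c("nuc", "cyt", "neg")`.
#' @export
twist_localization <- function(nuclear_detected, cytoplasmic_detected) {
  dplyr::case_when(
    nuclear_detected ~ "nuc",
    cytoplasmic_detected ~ "cyt",
    .default = "neg"
  )
}
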