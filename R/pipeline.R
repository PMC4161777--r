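#' Run the full single-cell phenotyping pipeline on one cytospin image
#'
#' Segments nuclei (DAPI) and cells (CK), measures morphology and
#' intensities, calls CTCs by cytokeratin positivity plus the morphology
#' criteria, and — for the triple panel — quantifies ALDH1 as an
#' exposure-equivalent level and scores TWIST localization, assigning each
#' CTC one of the four co-expression phenotypes. For the double panel
#' (DAPI / CK / CD45) the CD45-exclusion criterion is applied instead and
#' no marker phenotyping is performed.
#'
#' @param x A `cytospin` object (from [simulate_cytospin()] or
#'   [read_cytospin()]).
#' @param criteria A [ctc_criteria()]; `NULL` fields are filled per image
#'   (CK threshold from background, WBC reference from CK-negative cells).
#' @param calibration An [calibration_model()] for ALDH1 quantification.
#' @param min_nucleus_area Passed to [segment_nuclei()].
#' @param dilation_limit,k Passed to [segment_cells()].
#' @param twist_min_fraction Passed to [classify_twist()].
#' @param wbc_fallback Fallback WBC reference diameter (px) when fewer than
#'   20 CK-negative cells are present (default 10).
#' @return A tibble with one row per segmented cell: morphology, intensity
#'   summaries, `is_ctc`, `fail_reasons`, and (triple panel)
#'   `aldh1_exposure`, `aldh1_level`, `twist_loc`, `phenotype` (NA for
#'   non-CTCs).
#' @export
#' @examples
#' cs <- simulate_cytospin(sim_config(n_pbmc = 60, image_size = c(160, 160)),
#'                         spiked = tibble::tibble(aldh1_level = "high",
#'                                                 twist_loc = "nuc"))
#' res <- analyze_cytospin(cs)
#' dplyr::count(res, is_ctc, phenotype)
analyze_cytospin <- function(x, criteria = ctc_criteria(),
                             calibration = NULL,
                             min_nucleus_area = 20,
                             dilation_limit = 8, k = 5,
                             twist_min_fraction = 0.3,
                             wbc_fallback = 10) {
  stopifnot(inherits(x, "cytospin"))
  calibration <- calibration %||%
    (if (!is.null(x$config)) x$config$calibration else calibration_model())
  dapi <- channel(x, "dapi")
  ck <- channel(x, "ck")
  nuclei <- segment_nuclei(dapi, min_area = min_nucleus_area)
  cells_lab <- segment_cells(ck, nuclei, dilation_limit = dilation_limit, k = k)
  cells <- measure_cells(x, nuclei, cells_lab)
  if (nrow(cells) == 0) {
    cells$is_ctc <- logical()
    cells$fail_reasons <- list()
    cells$aldh1_exposure <- numeric()
    cells$aldh1_level <- character()
    cells$twist_loc <- character()
    cells$phenotype <- character()
    return(cells)
  }
  if (is.null(criteria$ck_positive_threshold)) {
    criteria$ck_positive_threshold <- ck_threshold(ck, nuclei, k)
  }
  if (is.null(criteria$wbc_diameter_reference)) {
    criteria$wbc_diameter_reference <- estimate_wbc_reference(
      cells, criteria$ck_positive_threshold, fallback = wbc_fallback)
  }
  if (x$config$panel %||% "triple" == "double") criteria$cd45_mode <- TRUE
  cells <- call_ctcs(cells, criteria)

  if ("twist" %in% x$channels && "aldh1" %in% x$channels) {
    tw <- classify_twist(channel(x, "twist"), nuclei, cells_lab,
                         min_positive_fraction = twist_min_fraction)
    cells <- left_join(cells, tw, by = "cell_id")
    cells$aldh1_exposure <- intensity_to_exposure(cells$aldh1_core_mean,
                                                  calibration)
    cells$aldh1_level <- classify_aldh1(cells$aldh1_exposure, calibration)
    cells$phenotype <- ifelse(
      cells$is_ctc,
      assign_phenotype(cells$aldh1_level, cells$twist_loc),
      NA_character_)
  }
  cells
}
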