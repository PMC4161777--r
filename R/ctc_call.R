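#' Criteria for calling a segmented cell a CTC
#'
#' A circulating tumour cell is a cytokeratin-positive cell that also
#' satisfies the cytomorphological criteria: size larger than white blood
#' cells and a high nuclear-to-cytoplasmic ratio. In the double-stain
#' quality-control panel, CD45 positivity additionally excludes
#' haematopoietic cells with ectopic cytokeratin expression. The source
#' assay states the morphology criteria qualitatively; here they are
#' quantified with documented, configurable defaults: a cell must be at
#' least `size_margin` times the per-image white-blood-cell reference
#' diameter, with N:C ratio at least `nc_ratio_min`.
#'
#' @param ck_positive_threshold Mean cytoplasmic CK intensity at or above
#'   which a cell is CK-positive. `NULL` to fill in per image (see
#'   [ck_threshold()]).
#' @param wbc_diameter_reference Reference white-blood-cell equivalent
#'   diameter in px. `NULL` to estimate per image with
#'   [estimate_wbc_reference()].
#' @param size_margin Multiplicative size factor over the WBC reference
#'   (>= 1; default 1.25).
#' @param nc_ratio_min Minimum N:C ratio (default 0.5).
#' @param cd45_mode If `TRUE`, require CD45 negativity (double-stain panel).
#' @param cd45_positive_threshold Mean CD45 intensity at or above which a
#'   cell counts as CD45-positive (leukocyte).
#' @return An object of class `ctc_criteria`.
#' @export
ctc_criteria <- function(ck_positive_threshold = NULL,
                         wbc_diameter_reference = NULL,
                         size_margin = 1.25,
                         nc_ratio_min = 0.5,
                         cd45_mode = FALSE,
                         cd45_positive_threshold = 0.25) {
  if (size_margin < 1) abort("size_margin must be >= 1")
  if (nc_ratio_min <= 0 || nc_ratio_min > 1) {
    abort("nc_ratio_min must be in (0, 1]")
  }
  structure(
    list(ck_positive_threshold = ck_positive_threshold,
         wbc_diameter_reference = wbc_diameter_reference,
         size_margin = size_margin, nc_ratio_min = nc_ratio_min,
         cd45_mode = cd45_mode,
         cd45_positive_threshold = cd45_positive_threshold),
    class = "ctc_criteria")
}

#' Estimate the white-blood-cell reference diameter of an image
#'
#' The size criterion ("larger than white blood cells") needs a per-image
#' reference scale. It is taken as a quantile (default: the median) of the
#' equivalent diameters of CK-negative cells, which on a cytospin are
#' overwhelmingly PBMCs. With fewer than `min_cells` CK-negative cells the
#' estimate is unreliable: an error asks for a configured `fallback`
#' constant instead.
#'
#' @param cells Tibble from [measure_cells()] (needs `ck_cyt_mean` and
#'   `equivalent_diameter`).
#' @param ck_positive_threshold CK threshold separating CK-positive cells.
#' @param probs Quantile of the CK-negative diameter distribution
#'   (default 0.5, the median).
#' @param min_cells Minimum number of CK-negative cells required.
#' @param fallback Reference diameter (px) to use when too few CK-negative
#'   cells are present; `NULL` (default) raises an error in that case.
#' @return Scalar reference diameter in px.
#' @export
estimate_wbc_reference <- function(cells, ck_positive_threshold,
                                   probs = 0.5, min_cells = 20,
                                   fallback = NULL) {
  cells <- as_tibble(cells)
  ckneg <- cells$equivalent_diameter[cells$ck_cyt_mean < ck_positive_threshold &
                                       !is.na(cells$ck_cyt_mean)]
  if (length(ckneg) < min_cells) {
    if (!is.null(fallback)) return(fallback)
    abort(sprintf(
      paste0("only %d CK-negative cells (< %d): too few to estimate the ",
             "white-blood-cell reference diameter; supply a configured ",
             "'fallback' constant"),
      length(ckneg), min_cells))
  }
  unname(quantile(ckneg, probs = probs, type = 7))
}

#' Call CTCs among segmented cells
#'
#' Applies the full criterion to every cell: mean cytoplasmic CK intensity
#' at or above the CK threshold, equivalent diameter at least
#' `size_margin` times the WBC reference, N:C ratio at least
#' `nc_ratio_min`, and (in `cd45_mode`) mean CD45 intensity below the CD45
#' threshold. `fail_reasons` lists every failed criterion per cell.
#'
#' @param cells Tibble from [measure_cells()].
#' @param criteria A [ctc_criteria()] with `ck_positive_threshold` and
#'   `wbc_diameter_reference` set (the pipeline wrapper fills them in from
#'   the image).
#' @return `cells` with columns `is_ctc` (logical) and `fail_reasons`
#'   (list of character vectors, empty for CTCs) appended.
#' @export
call_ctcs <- function(cells, criteria = ctc_criteria()) {
  stopifnot(inherits(criteria, "ctc_criteria"))
  cells <- as_tibble(cells)
  if (is.null(criteria$ck_positive_threshold) ||
      is.null(criteria$wbc_diameter_reference)) {
    abort("criteria must have ck_positive_threshold and wbc_diameter_reference set")
  }
  if (!"ck_cyt_mean" %in% names(cells)) {
    abort("cells must carry a ck_cyt_mean column (from measure_cells)")
  }
  ck_ok <- !is.na(cells$ck_cyt_mean) &
    cells$ck_cyt_mean >= criteria$ck_positive_threshold
  size_ok <- cells$equivalent_diameter >=
    criteria$size_margin * criteria$wbc_diameter_reference
  nc_ok <- cells$nc_ratio >= criteria$nc_ratio_min
  checks <- list("ck_negative" = !ck_ok,
                 "not_larger_than_wbc" = !size_ok,
                 "low_nc_ratio" = !nc_ok)
  if (criteria$cd45_mode) {
    if (!"cd45_cell_mean" %in% names(cells)) {
      abort("cd45_mode requires a cd45_cell_mean column")
    }
    checks[["cd45_positive"]] <-
      cells$cd45_cell_mean >= criteria$cd45_positive_threshold
  }
  fail <- purrr::map(seq_len(nrow(cells)), function(i) {
    names(checks)[vapply(checks, function(x) isTRUE(x[i]), logical(1))]
  })
  cells$is_ctc <- lengths(fail) == 0
  cells$fail_reasons <- fail
  cells
}
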