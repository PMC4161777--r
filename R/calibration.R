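#' ALDH1 exposure-time calibration model
#'
#' The imaging platform reports ALDH1 expression as the exposure time needed
#' to detect the fluorescent signal: a brighter cell needs a shorter exposure,
#' so lower values mean stronger expression. All reported exposure values lie
#' on a regular grid (multiples of `step`). The calibration model holds the
#' monotone decreasing map from mean fluorescence intensity to
#' exposure-equivalent units, plus the class cut-offs learned from labelled
#' control cells: `high` for exposures up to `high_max`, `low` for exposures
#' in `[low_min, low_max]`, `neg` (no expression) from `neg_min` upwards.
#'
#' The intensity-to-exposure map is `exposure = step * round(scale /
#' (intensity + eps) / step)`, clipped to `[grid_min, grid_max]`. Any strictly
#' decreasing map reproducing the calibration grid would do; this reciprocal
#' form is invertible, which lets the synthetic-image simulator render cells
#' whose measured intensities land exactly on a target exposure value.
#'
#' @param high_max Largest exposure still classified `high` (default 25).
#' @param low_min,low_max Exposure range classified `low` (defaults 30, 55).
#' @param neg_min Smallest exposure classified `neg` (default 60).
#' @param grid_min,grid_max Extremes of the exposure grid (defaults 5, 90,
#'   the full range observed on labelled control cells).
#' @param step Grid step in exposure units (default 5).
#' @param scale Constant of the reciprocal intensity-to-exposure map. The
#'   default (4.5) anchors the high-class median exposure (15) to a bright
#'   reference intensity of 0.3 on the 0-1 intensity scale.
#' @param eps Small constant guarding against division by zero.
#' @param class_stats Optional tibble of per-class summaries (columns
#'   `level`, `n`, `range_min`, `range_max`, `median`, `se`), filled in by
#'   [derive_cutoffs()].
#'
#' @return An object of class `aldh1_calibration`.
#' @seealso [derive_cutoffs()], [intensity_to_exposure()], [classify_aldh1()]
#' @export
#' @examples
#' cal <- calibration_model()
#' intensity_to_exposure(0.3, cal)   # bright reference -> 15 (high)
#' classify_aldh1(c(25, 45, 70), cal)
calibration_model <- function(high_max = 25, low_min = 30, low_max = 55,
                              neg_min = 60, grid_min = 5, grid_max = 90,
                              step = 5, scale = 4.5, eps = 1e-6,
                              class_stats = NULL) {
  vals <- c(grid_min = grid_min, high_max = high_max, low_min = low_min,
            low_max = low_max, neg_min = neg_min, grid_max = grid_max)
  if (any(vals %% step != 0)) {
    abort("all calibration cut-offs must be multiples of the grid step")
  }
  if (!(high_max < low_min && low_min <= low_max && low_max < neg_min)) {
    abort("calibration cut-offs must satisfy high_max < low_min <= low_max < neg_min")
  }
  if (grid_min > high_max || grid_max < neg_min) {
    abort("exposure grid must cover all three classes")
  }
  if (scale <= 0 || step <= 0) abort("scale and step must be positive")
  structure(
    list(high_max = high_max, low_min = low_min, low_max = low_max,
         neg_min = neg_min, grid_min = grid_min, grid_max = grid_max,
         step = step, scale = scale, eps = eps, class_stats = class_stats),
    class = "aldh1_calibration"
  )
}

#' @export
print.aldh1_calibration <- function(x, ...) {
  cat("ALDH1 exposure-time calibration\n")
  cat(sprintf("  grid: %d..%d step %d (exposure units; lower = stronger)\n",
              x$grid_min, x$grid_max, x$step))
  cat(sprintf("  high: <= %d   low: %d..%d   neg: >= %d\n",
              x$high_max, x$low_min, x$low_max, x$neg_min))
  if (!is.null(x$class_stats)) {
    cat("  fitted on labelled control cells:\n")
    print(as.data.frame(x$class_stats), row.names = FALSE)
  }
  invisible(x)
}

#' Convert mean fluorescence intensity to exposure-equivalent units
#'
#' Applies the calibration model's monotone decreasing reciprocal map and
#' quantizes the result to the model's exposure grid. Brighter input never
#' yields a larger output; zero intensity maps to the darkest grid value.
#'
#' @param intensity Numeric vector of non-negative mean intensities.
#' @param model An [calibration_model()] object.
#' @return Numeric vector of exposures on the model grid.
#' @export
intensity_to_exposure <- function(intensity, model = calibration_model()) {
  stopifnot(inherits(model, "aldh1_calibration"))
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    abort("intensity must be finite and non-negative")
  }
  raw <- model$scale / (intensity + model$eps)
  expo <- model$step * round(raw / model$step)
  pmin(pmax(expo, model$grid_min), model$grid_max)
}

#' Intensity at which the calibration maps to a given exposure
#'
#' Inverse of the centre of each quantization bin: the returned intensity is
#' mapped back to `exposure` by [intensity_to_exposure()]. Used by the
#' synthetic-image simulator to render cells at a target expression level.
#'
#' @param exposure Numeric vector of exposures on the model grid.
#' @inheritParams intensity_to_exposure
#' @return Numeric vector of intensities.
#' @export
exposure_to_intensity <- function(exposure, model = calibration_model()) {
  stopifnot(inherits(model, "aldh1_calibration"))
  check_on_grid(exposure, model)
  model$scale / exposure - model$eps
}

#' Classify ALDH1 expression level from an exposure measurement
#'
#' `high` for exposures at or below `high_max`, `low` within
#' `[low_min, low_max]`, `neg` at or above `neg_min`. Values off the model
#' grid, or in the gaps between classes, signal a mis-calibrated model and
#' raise an error (they are unreachable after quantization).
#'
#' @param exposure Numeric vector of exposures on the model grid.
#' @inheritParams intensity_to_exposure
#' @return Character vector with values in `c("high", "low", "neg")`.
#' @export
classify_aldh1 <- function(exposure, model = calibration_model()) {
  stopifnot(inherits(model, "aldh1_calibration"))
  check_on_grid(exposure, model)
  out <- rep(NA_character_, length(exposure))
  out[exposure <= model$high_max] <- "high"
  out[exposure >= model$low_min & exposure <= model$low_max] <- "low"
  out[exposure >= model$neg_min] <- "neg"
  if (anyNA(out)) {
    bad <- unique(exposure[is.na(out)])
    abort(sprintf(
      "exposure value(s) %s fall in a gap between calibrated classes; the model is mis-calibrated",
      paste(bad, collapse = ", ")))
  }
  out
}

check_on_grid <- function(exposure, model) {
  if (any(!is.finite(exposure))) abort("exposure must be finite")
  off <- exposure %% model$step != 0 |
    exposure < model$grid_min | exposure > model$grid_max
  if (any(off)) {
    abort(sprintf("exposure value(s) %s are off the calibration grid (%d..%d step %d)",
                  paste(unique(exposure[off]), collapse = ", "),
                  model$grid_min, model$grid_max, model$step))
  }
  invisible(TRUE)
}

#' Derive ALDH1 class cut-offs from labelled control cells
#'
#' Reproduces the calibration procedure: control cells labelled by eye as
#' high-, low- or non-expressing are measured in exposure units, and the
#' class boundaries observed on those cells become the classifier cut-offs.
#' Per-class range, median and standard error of the median-class location
#' (SE of the mean, as conventionally reported for these panels) are stored
#' in the returned model. Overlapping class ranges indicate unusable labels
#' and raise an error.
#'
#' @param measurements A data frame with columns `level` (one of `"high"`,
#'   `"low"`, `"neg"`) and `exposure` (values on the exposure grid), e.g.
#'   from [simulate_control_cells()].
#' @param step Grid step (default 5); all measurements must be multiples.
#' @param scale,eps Passed to [calibration_model()].
#' @return An `aldh1_calibration` whose cut-offs are the observed class
#'   boundaries and whose `class_stats` holds the per-class summaries.
#' @export
#' @examples
#' ctrl <- simulate_control_cells(seed = 1)
#' derive_cutoffs(ctrl)
derive_cutoffs <- function(measurements, step = 5, scale = 4.5, eps = 1e-6) {
  measurements <- as_tibble(measurements)
  if (!all(c("level", "exposure") %in% names(measurements))) {
    abort("measurements needs columns 'level' and 'exposure'")
  }
  lv <- c("high", "low", "neg")
  if (!all(lv %in% measurements$level)) {
    abort("measurements must contain all three classes: high, low, neg")
  }
  if (any(measurements$exposure %% step != 0)) {
    abort("all exposure measurements must lie on the grid (multiples of step)")
  }
  stats_tbl <- measurements |>
    filter(.data$level %in% lv) |>
    group_by(level = factor(.data$level, levels = lv)) |>
    summarise(n = dplyr::n(),
              range_min = min(.data$exposure),
              range_max = max(.data$exposure),
              median = stats::median(.data$exposure),
              se = if (dplyr::n() > 1) stats::sd(.data$exposure) / sqrt(dplyr::n()) else 0,
              .groups = "drop") |>
    arrange(.data$level)
  if (any(stats_tbl$n < 2)) {
    abort("each class needs at least 2 labelled measurements")
  }
  rg <- split(stats_tbl, stats_tbl$level)
  overlaps <- c(
    high_low = rg$high$range_max >= rg$low$range_min,
    low_neg  = rg$low$range_max >= rg$neg$range_min
  )
  if (any(overlaps)) {
    abort(sprintf(
      "labelled class ranges overlap (%s); cannot derive disjoint cut-offs",
      paste(names(overlaps)[overlaps], collapse = ", ")))
  }
  calibration_model(
    high_max = rg$high$range_max, low_min = rg$low$range_min,
    low_max = rg$low$range_max, neg_min = rg$neg$range_min,
    grid_min = rg$high$range_min, grid_max = rg$neg$range_max,
    step = step, scale = scale, eps = eps, class_stats = stats_tbl
  )
}
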