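#' Write a cytospin image to multi-page TIFF with a metadata sidecar
#'
#' Channels are written as successive TIFF pages in the order listed in the
#' sidecar YAML (`<path>.yml`), which also records the pixel size. Ground
#' truth, when present, is written to `<path>.truth.csv`.
#'
#' @param x A `cytospin`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cytospin <- function(x, path) {
  stopifnot(inherits(x, "cytospin"))
  pages <- purrr::map(x$channels, function(ch) channel(x, ch))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(
    list(channels = as.list(x$channels), pixel_size_um = x$pixel_size),
    paste0(path, ".yml"))
  if (!is.null(x$ground_truth) && nrow(x$ground_truth)) {
    readr::write_csv(x$ground_truth, paste0(path, ".truth.csv"),
                     progress = FALSE)
  }
  invisible(path)
}

#' Read a cytospin image written by [write_cytospin()]
#'
#' @param path TIFF path; `<path>.yml` must exist and name the channels.
#' @return A `cytospin` (without a simulation config; the default
#'   calibration applies downstream unless one is supplied explicitly).
#' @export
read_cytospin <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  channels <- unlist(meta$channels)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channels)) {
    abort("TIFF page count does not match the sidecar channel list")
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  img <- array(0, dim = c(H, W, length(channels)),
               dimnames = list(NULL, NULL, channels))
  for (i in seq_along(pages)) img[, , i] <- pages[[i]]
  truth_path <- paste0(path, ".truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  structure(list(image = img, channels = channels,
                 pixel_size = meta$pixel_size_um %||% 1,
                 ground_truth = truth, config = NULL),
            class = "cytospin")
}

#' Write / read a patient-profile counts table
#'
#' Plain CSV with the canonical header `patient_id,setting,total_ctc,
#' n_high_nuc,n_high_cytneg,n_lowneg_nuc,n_lowneg_cytneg` (plus
#' `pbmcs_analyzed` when present).
#'
#' @param profiles Patient-profile tibble.
#' @param path CSV path.
#' @return `path` invisibly; `read_cohort_csv()` returns the tibble.
#' @export
write_cohort_csv <- function(profiles, path) {
  profiles <- validate_profiles(profiles)
  lead <- intersect(c("patient_id", "setting", "total_ctc", count_cols(),
                      "pbmcs_analyzed"), names(profiles))
  readr::write_csv(profiles[lead], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  validate_profiles(readr::read_csv(path, show_col_types = FALSE,
                                    progress = FALSE))
}

#' Write per-cell pipeline results to CSV
#'
#' Flattens the `fail_reasons` list-column to a `;`-separated string.
#'
#' @param cells Tibble from [analyze_cytospin()] or [call_ctcs()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(cells, path) {
  cells <- as_tibble(cells)
  if ("fail_reasons" %in% names(cells)) {
    cells$fail_reasons <- vapply(cells$fail_reasons, paste,
                                 character(1), collapse = ";")
  }
  readr::write_csv(cells, path, progress = FALSE)
  invisible(path)
}
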