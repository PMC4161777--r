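#' Segment nuclei from a DAPI channel
#'
#' Thresholds the DAPI channel (Otsu threshold plus a configurable offset),
#' fills holes, and splits touching nuclei by a watershed on the distance
#' transform. Objects smaller than `min_area` are discarded. A blank channel
#' yields an empty segmentation, not an error.
#'
#' @param dapi H x W numeric matrix (DAPI channel, intensities in 0-1).
#' @param min_area Minimum nucleus area in px^2 (> 0).
#' @param offset Added to the Otsu threshold (default 0).
#' @param tolerance Watershed tolerance (object height needed to stay a
#'   separate nucleus; default 1 on the distance-transform scale).
#' @return Integer label matrix (0 = background; labels 1..n).
#' @export
segment_nuclei <- function(dapi, min_area = 20, offset = 0, tolerance = 1) {
  stopifnot(is.matrix(dapi))
  if (min_area <= 0) abort("min_area must be > 0")
  if (max(dapi) - min(dapi) < 1e-8) {
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  th <- EBImage::otsu(EBImage::Image(dapi), range = c(0, max(dapi, 1)))
  mask <- dapi > th + offset
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dist <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dist, tolerance = tolerance, ext = 1)
  lab <- as.integer(round(as.vector(EBImage::imageData(labels))))
  keep_small_out(matrix(lab, nrow(dapi), ncol(dapi)), min_area)
}

# Drop labels below an area threshold and relabel consecutively.
keep_small_out <- function(lab, min_area) {
  if (!any(lab > 0)) return(lab)
  areas <- tabulate(lab)
  keep <- which(areas >= min_area)
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Grow cell masks from nuclei using the cytokeratin channel
#'
#' Each cell mask is its nucleus plus the cytokeratin(CK)-positive region
#' connected to it, limited to pixels within `dilation_limit` of the
#' nucleus; contested pixels between neighbouring cells are assigned to the
#' nearest nucleus. CK positivity is called at `mean + k * sd` of the
#' non-nucleus background pixels. Cells without CK signal (e.g. PBMCs)
#' receive a default thin cytoplasmic rim: the nucleus dilated by
#' `base_radius` pixels. Cell labels match the nucleus labels.
#'
#' @param ck H x W numeric matrix (pan-cytokeratin channel).
#' @param nuclei Integer label matrix from [segment_nuclei()].
#' @param dilation_limit Maximum distance (px) a cell may extend beyond its
#'   nucleus (default 8).
#' @param k Multiplier of the background sd for the CK-positivity threshold
#'   (default 5).
#' @param base_radius Default cytoplasmic rim for CK-negative cells (px).
#' @return Integer label matrix of cells (same labels as `nuclei`).
#' @export
segment_cells <- function(ck, nuclei, dilation_limit = 8, k = 5,
                          base_radius = 1) {
  stopifnot(is.matrix(ck), is.matrix(nuclei),
            all(dim(ck) == dim(nuclei)))
  if (!any(nuclei > 0)) return(matrix(0L, nrow(ck), ncol(ck)))
  th <- ck_threshold(ck, nuclei, k)
  ck_pos <- ck > th
  # distance from every pixel to the nearest nucleus pixel
  dist_to_nuc <- EBImage::imageData(EBImage::distmap(
    EBImage::Image((nuclei == 0) * 1)))
  grow <- (nuclei > 0) | (ck_pos & dist_to_nuc <= dilation_limit) |
    (dist_to_nuc <= base_radius)
  cells <- EBImage::propagate(
    x = EBImage::Image(ck), seeds = EBImage::Image(nuclei),
    mask = EBImage::Image(grow * 1), lambda = 100)
  out <- matrix(as.integer(round(as.vector(EBImage::imageData(cells)))),
                nrow(ck), ncol(ck))
  # keep only components connected to their own nucleus in each label
  out
}

#' CK-positivity threshold from background pixels
#'
#' `mean + k * sd` of the cytokeratin intensities outside all nuclei (a
#' robust upper bound on background when CK-positive cells are rare).
#'
#' @inheritParams segment_cells
#' @return Scalar threshold.
#' @export
ck_threshold <- function(ck, nuclei, k = 5) {
  bg <- ck[nuclei == 0]
  if (!length(bg)) bg <- as.vector(ck)
  mean(bg) + k * sd(bg)
}

#' Measure morphology and per-channel intensities of segmented cells
#'
#' For every labelled cell: nucleus and cell areas (px^2), centroid,
#' equivalent diameter (diameter of the circle with the cell's area), the
#' nuclear-to-cell area ratio (N:C, in (0, 1]), a border flag, and, per
#' image channel, mean and total intensity over the nucleus mask, the
#' cytoplasm mask (cell minus nucleus) and the whole cell, plus an interior
#' ("core") cell mean computed on the cell mask eroded by `core_erosion`
#' pixels. The core mean avoids partial-coverage edge pixels and is the
#' measurement used for exposure-equivalent ALDH1 quantification; it falls
#' back to the whole-cell mean for cells too small to erode.
#'
#' @param image H x W x C array with named channels, or a `cytospin`.
#' @param nuclei,cells Label matrices from [segment_nuclei()] and
#'   [segment_cells()] (matching labels).
#' @param core_erosion Erosion depth in px for the interior mean (default 2).
#' @return A tibble with one row per cell: `cell_id`, `row`, `col`,
#'   `nucleus_area`, `cell_area`, `equivalent_diameter`, `nc_ratio`,
#'   `on_border`, and `<channel>_{nuc,cyt,cell}_{mean,total}` columns plus
#'   `<channel>_core_mean`.
#' @export
measure_cells <- function(image, nuclei, cells, core_erosion = 2) {
  if (inherits(image, "cytospin")) image <- image$image
  stopifnot(length(dim(image)) == 3)
  ch_names <- dimnames(image)[[3]] %||% paste0("ch", seq_len(dim(image)[3]))
  H <- dim(image)[1]; W <- dim(image)[2]
  stopifnot(all(dim(nuclei) == c(H, W)), all(dim(cells) == c(H, W)))
  n <- max(cells, nuclei)
  if (n == 0) return(empty_cells_tbl(ch_names))

  cell_v <- as.vector(cells)
  nuc_v <- as.vector(nuclei)
  idx_cell <- which(cell_v > 0)
  lab_cell <- cell_v[idx_cell]
  rows_all <- ((idx_cell - 1) %% H) + 1
  cols_all <- ((idx_cell - 1) %/% H) + 1

  cell_area <- tab_n(lab_cell, n)
  nuc_area <- tab_n(nuc_v[nuc_v > 0], n)
  if (any(cell_area == 0 & nuc_area > 0)) {
    abort("every nucleus label must appear in the cell label image")
  }
  sum_r <- rowsum_n(rows_all, lab_cell, n)
  sum_c <- rowsum_n(cols_all, lab_cell, n)
  centroid_r <- sum_r / pmax(cell_area, 1)
  centroid_c <- sum_c / pmax(cell_area, 1)
  border <- tab_n(lab_cell[rows_all == 1 | rows_all == H |
                             cols_all == 1 | cols_all == W], n) > 0

  out <- tibble(
    cell_id = seq_len(n),
    row = centroid_r, col = centroid_c,
    nucleus_area = nuc_area, cell_area = cell_area,
    equivalent_diameter = 2 * sqrt(cell_area / pi),
    nc_ratio = ifelse(cell_area > 0, nuc_area / cell_area, NA_real_),
    on_border = border
  )
  if (any(out$nucleus_area == 0)) {
    abort("cell label without a nucleus: nuclei and cells labels must match")
  }

  in_nuc <- nuc_v[idx_cell] == lab_cell   # pixel belongs to its own nucleus
  core_masks <- core_pixels(cells, n, core_erosion)
  for (ch in seq_along(ch_names)) {
    v <- as.vector(image[, , ch])[idx_cell]
    tot_cell <- rowsum_n(v, lab_cell, n)
    tot_nuc <- rowsum_n(v[in_nuc], lab_cell[in_nuc], n)
    area_nuc <- tab_n(lab_cell[in_nuc], n)
    tot_cyt <- tot_cell - tot_nuc
    area_cyt <- cell_area - area_nuc
    core_mean <- vapply(seq_len(n), function(i) {
      px <- core_masks[[i]]
      if (length(px)) mean(as.vector(image[, , ch])[px]) else tot_cell[i] / cell_area[i]
    }, numeric(1))
    nm <- ch_names[ch]
    out[[paste0(nm, "_nuc_mean")]] <- ifelse(area_nuc > 0, tot_nuc / area_nuc, NA_real_)
    out[[paste0(nm, "_nuc_total")]] <- tot_nuc
    out[[paste0(nm, "_cyt_mean")]] <- ifelse(area_cyt > 0, tot_cyt / area_cyt, NA_real_)
    out[[paste0(nm, "_cyt_total")]] <- tot_cyt
    out[[paste0(nm, "_cell_mean")]] <- tot_cell / cell_area
    out[[paste0(nm, "_cell_total")]] <- tot_cell
    out[[paste0(nm, "_core_mean")]] <- core_mean
  }
  out
}

empty_cells_tbl <- function(ch_names) {
  out <- tibble(cell_id = integer(), row = numeric(), col = numeric(),
                nucleus_area = numeric(), cell_area = numeric(),
                equivalent_diameter = numeric(), nc_ratio = numeric(),
                on_border = logical())
  for (nm in ch_names) {
    for (sfx in c("_nuc_mean", "_nuc_total", "_cyt_mean", "_cyt_total",
                  "_cell_mean", "_cell_total", "_core_mean")) {
      out[[paste0(nm, sfx)]] <- numeric()
    }
  }
  out
}

tab_n <- function(x, n) tabulate(x, nbins = n)

rowsum_n <- function(v, g, n) {
  out <- numeric(n)
  if (length(v)) {
    rs <- rowsum(v, g)
    out[as.integer(rownames(rs))] <- rs[, 1]
  }
  out
}

# Linear indices of each cell's interior (mask eroded by `depth` px),
# computed per label on a cropped bounding box.
core_pixels <- function(cells, n, depth) {
  H <- nrow(cells); W <- ncol(cells)
  idx <- which(cells > 0)
  lab <- cells[idx]
  rows <- ((idx - 1) %% H) + 1
  cols <- ((idx - 1) %/% H) + 1
  by_lab_idx <- split(seq_along(idx), lab)
  out <- rep(list(integer(0)), n)
  for (nm in names(by_lab_idx)) {
    i <- as.integer(nm)
    sel <- by_lab_idx[[nm]]
    r0 <- min(rows[sel]); r1 <- max(rows[sel])
    c0 <- min(cols[sel]); c1 <- max(cols[sel])
    sub <- matrix(0, r1 - r0 + 1, c1 - c0 + 1)
    sub[cbind(rows[sel] - r0 + 1, cols[sel] - c0 + 1)] <- 1
    if (depth > 0) {
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(sub)))
      keep <- dm > depth
    } else {
      keep <- sub > 0
    }
    kr <- which(keep, arr.ind = TRUE)
    if (nrow(kr)) {
      out[[i]] <- (kr[, 2] + c0 - 2) * H + (kr[, 1] + r0 - 1)
    }
  }
  out
}
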