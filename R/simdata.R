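#' Configuration for synthetic cytospin images
#'
#' Describes one synthetic field of view: a dense lawn of peripheral-blood
#' mononuclear cells (PBMCs) with, optionally, a few spiked tumour cells of
#' known phenotype. Tumour cells are rendered strictly larger than PBMCs,
#' cytokeratin-positive in the cytoplasm, with ALDH1 intensity chosen so the
#' exposure-equivalent transform lands on the calibrated grid, and TWIST in
#' the nucleus and/or cytoplasm according to the ground-truth localization.
#' PBMCs are cytokeratin-negative but carry non-zero ALDH1/TWIST background,
#' as real PBMCs do.
#'
#' Cells are flat-top hard-edged discs (a disc nucleus plus an annular
#' cytoplasm, pixel-centre sampling): the rendered geometry is then an exact
#' ground truth, so measured areas and N:C ratios can be validated against
#' analytic disc geometry. Intensities live on a 0-1 scale (a 16-bit
#' image divided by its full range); one pixel represents a nominal 1 um.
#'
#' @param image_size Integer vector `c(H, W)` in pixels.
#' @param n_pbmc Number of background PBMCs to place.
#' @param pbmc_nucleus_diameter Named vector `c(mean =, sd =)` in pixels
#'   (default mean 8, sd 0.8). PBMC cell extent is the nucleus plus a thin
#'   rim of cytoplasm.
#' @param tumour_cell_diameter Named vector `c(mean =, sd =)` in pixels
#'   (default mean 18, sd 1.5); the mean must exceed the PBMC mean.
#' @param tumour_nc_ratio Target nuclear-to-cell area ratio of tumour cells,
#'   in (0, 1] (default 0.8).
#' @param pbmc_marker_background Named list with elements `aldh1` and
#'   `twist`, each `c(min =, max =)` intensity bounds of the uniform PBMC
#'   background expression (defaults 0.02-0.06: detectable, far below any
#'   calibrated expression class).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (default 0.02 on the 0-1 scale).
#' @param dapi_intensity,ck_intensity,twist_intensity Flat-top rendering
#'   intensities of the nuclear stain, cytokeratin and TWIST signals.
#' @param panel `"triple"` (DAPI / CK / ALDH1 / TWIST) or `"double"`
#'   (DAPI / CK / CD45, the leukocyte-exclusion quality-control stain,
#'   where PBMCs are CD45-positive and tumour cells CD45-negative).
#' @param cd45_intensity Flat-top CD45 intensity on PBMCs (double panel).
#' @param calibration An [calibration_model()] used to translate true ALDH1
#'   levels into rendered intensities.
#' @param seed Integer seed; fully determines the generated image.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(image_size = c(512L, 512L),
                       n_pbmc = 500L,
                       pbmc_nucleus_diameter = c(mean = 8, sd = 0.8),
                       tumour_cell_diameter = c(mean = 18, sd = 1.5),
                       tumour_nc_ratio = 0.8,
                       pbmc_marker_background = list(
                         aldh1 = c(min = 0.02, max = 0.06),
                         twist = c(min = 0.02, max = 0.06)),
                       noise_sd = 0.02,
                       dapi_intensity = 0.8,
                       ck_intensity = 0.5,
                       twist_intensity = 0.45,
                       panel = c("triple", "double"),
                       cd45_intensity = 0.5,
                       calibration = calibration_model(),
                       seed = 1L) {
  panel <- match.arg(panel)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(!is.finite(image_size)) ||
      any(image_size <= 0)) {
    abort("image_size must be two positive integers (H, W)")
  }
  if (n_pbmc < 0) abort("n_pbmc must be >= 0")
  if (pbmc_nucleus_diameter[["sd"]] < 0 || tumour_cell_diameter[["sd"]] < 0) {
    abort("diameter sds must be >= 0")
  }
  if (tumour_cell_diameter[["mean"]] <= pbmc_nucleus_diameter[["mean"]]) {
    abort("tumour cell diameter mean must exceed the PBMC nucleus diameter mean")
  }
  if (tumour_nc_ratio <= 0 || tumour_nc_ratio > 1) {
    abort("tumour_nc_ratio must be in (0, 1]")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  stopifnot(inherits(calibration, "aldh1_calibration"))
  structure(
    list(image_size = image_size, n_pbmc = as.integer(n_pbmc),
         pbmc_nucleus_diameter = pbmc_nucleus_diameter,
         tumour_cell_diameter = tumour_cell_diameter,
         tumour_nc_ratio = tumour_nc_ratio,
         pbmc_marker_background = pbmc_marker_background,
         noise_sd = noise_sd, dapi_intensity = dapi_intensity,
         ck_intensity = ck_intensity, twist_intensity = twist_intensity,
         panel = panel, cd45_intensity = cd45_intensity,
         calibration = calibration, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic per-cell / per-stage RNG streams: the stream of cell k is a
# pure function of (seed, kind, k), so adding a spiked cell never reshuffles
# the attributes or position of any other cell.
derive_seed <- function(seed, kind, idx) {
  base <- (as.numeric(seed) %% 2147483647) + 1
  k <- switch(kind, tumour = 1, pbmc = 2, noise = 3, truth = 4, stage = 5, 6)
  as.integer((base * 48271 + k * 1664525 + as.numeric(idx) * 22695477) %%
               2147483629)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a multi-channel cytospin field of view
#'
#' Renders `config$n_pbmc` PBMCs plus the given spiked tumour cells onto a
#' multi-channel image and returns both the image and the ground truth for
#' every rendered cell. Cell centres are placed by rejection sampling with a
#' hard non-overlap constraint; if a centre cannot be placed (or two
#' requested spiked centres collide) the packing limit is reported as an
#' error. The same seed and configuration always produce a bit-identical
#' image.
#'
#' @param config A [sim_config()].
#' @param spiked A data frame of tumour cells to spike, with columns
#'   `aldh1_level` (`"high"`, `"low"`, `"neg"`) and `twist_loc` (`"nuc"`,
#'   `"cyt"`, `"neg"`), and optional `row`, `col` centres (auto-placed when
#'   missing). `NULL` or zero rows means a pure-PBMC image.
#' @return A `cytospin` object: list with `image` (H x W x C array, channels
#'   named `dapi`, `ck`, `aldh1`, `twist` — or `dapi`, `ck`, `cd45` for the
#'   double panel), `channels`, `pixel_size`, `ground_truth` (tibble: one
#'   row per rendered cell) and `config`.
#' @export
#' @examples
#' cs <- simulate_cytospin(sim_config(n_pbmc = 50, image_size = c(128, 128)),
#'                         spiked = tibble::tibble(aldh1_level = "high",
#'                                                 twist_loc = "nuc"))
#' cs$ground_truth
simulate_cytospin <- function(config, spiked = NULL) {
  stopifnot(inherits(config, "sim_config"))
  H <- config$image_size[1]; W <- config$image_size[2]
  channels <- if (config$panel == "triple") {
    c("dapi", "ck", "aldh1", "twist")
  } else {
    c("dapi", "ck", "cd45")
  }
  cal <- config$calibration

  spiked <- normalize_spiked(spiked)
  n_t <- nrow(spiked)

  placed_r <- numeric(0); placed_c <- numeric(0); placed_rad <- numeric(0)
  place <- function(radius, rng_seed, fixed_r = NA, fixed_c = NA) {
    margin <- radius + 2
    if (2 * margin >= min(H, W)) {
      abort("image too small for the requested cell size")
    }
    if (!is.na(fixed_r)) {
      if (fixed_r < margin || fixed_r > H - margin ||
          fixed_c < margin || fixed_c > W - margin) {
        abort("spiked cell centre out of image bounds")
      }
      if (length(placed_r) &&
          any(sqrt((placed_r - fixed_r)^2 + (placed_c - fixed_c)^2) <
                placed_rad + radius + 1)) {
        abort("spiked cell centres overlap beyond the packing limit")
      }
      return(c(fixed_r, fixed_c))
    }
    res <- with_local_seed(rng_seed, {
      ans <- NULL
      for (i in seq_len(400)) {
        r <- runif(1, margin, H - margin)
        c <- runif(1, margin, W - margin)
        if (!length(placed_r) ||
            all(sqrt((placed_r - r)^2 + (placed_c - c)^2) >=
                  placed_rad + radius + 1)) {
          ans <- c(r, c)
          break
        }
      }
      ans
    })
    if (is.null(res)) {
      abort("could not place cell: packing limit exceeded (too many cells for the image)")
    }
    res
  }

  truth <- vector("list", n_t + config$n_pbmc)
  img <- array(0, dim = c(H, W, length(channels)),
               dimnames = list(NULL, NULL, channels))

  add_disc <- function(channel, cr, cc, radius, value, inner = 0) {
    r0 <- max(1L, floor(cr - radius - 1)); r1 <- min(H, ceiling(cr + radius + 1))
    c0 <- max(1L, floor(cc - radius - 1)); c1 <- min(W, ceiling(cc + radius + 1))
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
    m <- if (inner > 0) d2 <= radius^2 & d2 > inner^2 else d2 <= radius^2
    patch <- img[rows, cols, channel]
    patch[m] <- patch[m] + value
    img[rows, cols, channel] <<- patch
  }

  # tumour cells first: their streams are keyed by their own index
  for (i in seq_len(n_t)) {
    srand <- derive_seed(config$seed, "tumour", i)
    pars <- with_local_seed(srand, {
      d <- rnorm(1, config$tumour_cell_diameter[["mean"]],
                 config$tumour_cell_diameter[["sd"]])
      list(diam = max(d, config$pbmc_nucleus_diameter[["mean"]] + 2),
           ck = rnorm(1, config$ck_intensity, 0.03),
           expo = sample_exposure(spiked$aldh1_level[i], cal),
           twist_also_cyt = runif(1) < 0.5)
    })
    rc <- pars$diam / 2
    rn <- rc * sqrt(config$tumour_nc_ratio)
    pos <- place(rc, derive_seed(config$seed, "tumour", i + 10000L),
                 spiked$row[i], spiked$col[i])
    add_disc("dapi", pos[1], pos[2], rn, config$dapi_intensity)
    add_disc("ck", pos[1], pos[2], rc, pars$ck, inner = rn)
    if (config$panel == "triple") {
      add_disc("aldh1", pos[1], pos[2], rc, exposure_to_intensity(pars$expo, cal))
      tl <- spiked$twist_loc[i]
      if (tl == "nuc") {
        add_disc("twist", pos[1], pos[2], rn, config$twist_intensity)
        if (pars$twist_also_cyt) {
          add_disc("twist", pos[1], pos[2], rc, config$twist_intensity, inner = rn)
        }
      } else if (tl == "cyt") {
        add_disc("twist", pos[1], pos[2], rc, config$twist_intensity, inner = rn)
      }
    }
    placed_r <- c(placed_r, pos[1]); placed_c <- c(placed_c, pos[2])
    placed_rad <- c(placed_rad, rc)
    truth[[i]] <- tibble(
      cell = i, row = pos[1], col = pos[2], cell_kind = "tumour",
      diameter = pars$diam, nucleus_diameter = 2 * rn,
      ck_positive = TRUE, true_aldh1_level = spiked$aldh1_level[i],
      true_aldh1_exposure = pars$expo, true_twist_loc = spiked$twist_loc[i])
  }

  for (j in seq_len(config$n_pbmc)) {
    srand <- derive_seed(config$seed, "pbmc", j)
    pars <- with_local_seed(srand, {
      d <- rnorm(1, config$pbmc_nucleus_diameter[["mean"]],
                 config$pbmc_nucleus_diameter[["sd"]])
      bg <- config$pbmc_marker_background
      list(diam = max(d, 5),
           aldh1 = runif(1, bg$aldh1[["min"]], bg$aldh1[["max"]]),
           twist = runif(1, bg$twist[["min"]], bg$twist[["max"]]))
    })
    rn <- pars$diam / 2
    rcell <- rn + 1.5  # thin cytoplasmic rim
    pos <- place(rcell, derive_seed(config$seed, "pbmc", j + 10000L))
    add_disc("dapi", pos[1], pos[2], rn, config$dapi_intensity)
    if (config$panel == "triple") {
      add_disc("aldh1", pos[1], pos[2], rcell, pars$aldh1)
      add_disc("twist", pos[1], pos[2], rcell, pars$twist)
    } else {
      add_disc("cd45", pos[1], pos[2], rcell, config$cd45_intensity)
    }
    placed_r <- c(placed_r, pos[1]); placed_c <- c(placed_c, pos[2])
    placed_rad <- c(placed_rad, rcell)
    truth[[n_t + j]] <- tibble(
      cell = n_t + j, row = pos[1], col = pos[2], cell_kind = "pbmc",
      diameter = pars$diam, nucleus_diameter = pars$diam,
      ck_positive = FALSE, true_aldh1_level = "neg",
      true_aldh1_exposure = NA_real_, true_twist_loc = "neg")
  }

  if (config$noise_sd > 0) {
    noise <- with_local_seed(derive_seed(config$seed, "noise", 0L),
                             rnorm(length(img), 0, config$noise_sd))
    img <- img + noise
  }
  img[img < 0] <- 0; img[img > 1] <- 1

  structure(
    list(image = img, channels = channels, pixel_size = 1,
         ground_truth = bind_rows(truth), config = config),
    class = "cytospin"
  )
}

normalize_spiked <- function(spiked) {
  if (is.null(spiked) || (is.data.frame(spiked) && nrow(spiked) == 0)) {
    return(tibble(aldh1_level = character(), twist_loc = character(),
                  row = numeric(), col = numeric()))
  }
  spiked <- as_tibble(spiked)
  if (!all(c("aldh1_level", "twist_loc") %in% names(spiked))) {
    abort("spiked needs columns 'aldh1_level' and 'twist_loc'")
  }
  if (!all(spiked$aldh1_level %in% c("high", "low", "neg"))) {
    abort("aldh1_level must be one of high, low, neg")
  }
  if (!all(spiked$twist_loc %in% c("nuc", "cyt", "neg"))) {
    abort("twist_loc must be one of nuc, cyt, neg")
  }
  if (!"row" %in% names(spiked)) spiked$row <- NA_real_
  if (!"col" %in% names(spiked)) spiked$col <- NA_real_
  spiked
}

# Draw a true exposure value uniformly from the grid span of a level.
sample_exposure <- function(level, cal) {
  rng <- switch(level,
                high = c(cal$grid_min, cal$high_max),
                low = c(cal$low_min, cal$low_max),
                neg = c(cal$neg_min, cal$grid_max))
  grid <- seq(rng[1], rng[2], by = cal$step)
  grid[sample.int(length(grid), 1)]
}

#' @export
print.cytospin <- function(x, ...) {
  cat(sprintf("cytospin image: %d x %d px, channels: %s\n",
              dim(x$image)[1], dim(x$image)[2],
              paste(x$channels, collapse = ", ")))
  gt <- x$ground_truth
  cat(sprintf("  ground truth: %d cells (%d tumour, %d PBMC)\n",
              nrow(gt), sum(gt$cell_kind == "tumour"),
              sum(gt$cell_kind == "pbmc")))
  invisible(x)
}

#' Extract one channel of a cytospin image as a matrix
#'
#' @param x A `cytospin` object.
#' @param name Channel name (e.g. `"dapi"`).
#' @return An H x W numeric matrix.
#' @export
channel <- function(x, name) {
  stopifnot(inherits(x, "cytospin"))
  if (!name %in% x$channels) {
    abort(sprintf("no channel '%s' (have: %s)", name,
                  paste(x$channels, collapse = ", ")))
  }
  x$image[, , name]
}

#' Simulate a spike-in recovery experiment
#'
#' Models the cell-spiking experiment used to estimate the sensitivity of
#' rare-cell detection: a known number of tumour cells is spiked into a PBMC
#' background and each cell independently survives a sequence of processing
#' stages (density-gradient separation, cytocentrifugation, staining,
#' detection), each with its own retention probability. Recovery is the
#' fraction of spiked cells that survive all stages, so the expected
#' recovery is the product of the stage retentions.
#'
#' @param concentration Spiked cells per 10^6 PBMCs (> 0).
#' @param stage_retention Numeric vector of per-stage survival
#'   probabilities, each in `[0, 1]`; must be non-empty.
#' @param n_replicates Number of independent replicates.
#' @param n_pbmc PBMCs per replicate (default 10^6).
#' @param seed Integer seed.
#' @return A tibble with one row per replicate: `replicate`, `n_spiked`,
#'   `n_recovered`, `recovery_pct`.
#' @export
#' @examples
#' simulate_spike_in(100, c(0.9, 0.9), n_replicates = 5, seed = 1)
simulate_spike_in <- function(concentration, stage_retention,
                              n_replicates = 3, n_pbmc = 1e6, seed = 1L) {
  if (length(stage_retention) == 0) {
    abort("stage_retention must contain at least one stage")
  }
  if (any(stage_retention < 0 | stage_retention > 1)) {
    abort("stage retention probabilities must be in [0, 1]")
  }
  if (concentration <= 0) abort("concentration must be > 0")
  n_spiked <- max(1L, round(concentration * n_pbmc / 1e6))
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    surv <- with_local_seed(derive_seed(seed, "stage", r), {
      s <- n_spiked
      for (p in stage_retention) s <- rbinom(1, s, p)
      s
    })
    tibble(replicate = r, n_spiked = n_spiked, n_recovered = surv,
           recovery_pct = 100 * surv / n_spiked)
  })
  bind_rows(rows)
}

#' Simulate patient-level CTC phenotype counts for a cohort
#'
#' Generates the tabular structure of a patient cohort: each patient is
#' CTC-positive with probability `detection_rate`; detected patients draw a
#' total CTC count from `ctc_count_dist` (support on positive integers) and
#' split it across the four co-expression phenotypes by a multinomial draw
#' with `phenotype_probs`.
#'
#' @param setting Cohort label, `"early"` or `"metastatic"`. Supplies
#'   defaults for the other parameters via [cohort_defaults()].
#' @param n_patients Number of patients.
#' @param detection_rate Probability that a patient has at least one CTC.
#' @param phenotype_probs Length-4 probability vector over the phenotypes
#'   `high_nuc`, `high_cytneg`, `lowneg_nuc`, `lowneg_cytneg`; must sum to 1.
#' @param ctc_count_dist Function `n -> n positive integer CTC totals` for
#'   detected patients. Default: 1 + a negative-binomial count, matched in
#'   location to the setting's observed per-patient CTC burden.
#' @param pbmcs_analyzed Reporting denominator per patient (default 5e5).
#' @param seed Integer seed.
#' @return A tibble of patient profiles: `patient_id`, `setting`,
#'   `pbmcs_analyzed`, the four phenotype counts `n_high_nuc`,
#'   `n_high_cytneg`, `n_lowneg_nuc`, `n_lowneg_cytneg`, and `total_ctc`
#'   (zero for undetected patients).
#' @export
#' @examples
#' simulate_cohort("metastatic", n_patients = 50, seed = 1)
simulate_cohort <- function(setting = c("early", "metastatic"),
                            n_patients,
                            detection_rate = NULL,
                            phenotype_probs = NULL,
                            ctc_count_dist = NULL,
                            pbmcs_analyzed = 500000L,
                            seed = 1L) {
  setting <- match.arg(setting)
  defs <- cohort_defaults(setting)
  detection_rate <- detection_rate %||% defs$detection_rate
  phenotype_probs <- phenotype_probs %||% defs$phenotype_probs
  ctc_count_dist <- ctc_count_dist %||% defs$ctc_count_dist
  if (detection_rate < 0 || detection_rate > 1) {
    abort("detection_rate must be in [0, 1]")
  }
  if (length(phenotype_probs) != 4 || any(phenotype_probs < 0) ||
      abs(sum(phenotype_probs) - 1) > 1e-8) {
    abort("phenotype_probs must be 4 non-negative values summing to 1")
  }
  with_local_seed(derive_seed(seed, "cohort", 0L), {
    detected <- rbinom(n_patients, 1, detection_rate) == 1
    totals <- integer(n_patients)
    if (any(detected)) {
      tot <- ctc_count_dist(sum(detected))
      if (any(tot < 1 | tot != round(tot))) {
        abort("ctc_count_dist must return positive integers")
      }
      totals[detected] <- as.integer(tot)
    }
    counts <- matrix(0L, nrow = n_patients, ncol = 4)
    for (i in which(detected)) {
      counts[i, ] <- as.integer(rmultinom(1, totals[i], phenotype_probs))
    }
    tibble(
      patient_id = sprintf("%s_%03d", substr(setting, 1, 1), seq_len(n_patients)),
      setting = setting, pbmcs_analyzed = as.integer(pbmcs_analyzed),
      n_high_nuc = counts[, 1], n_high_cytneg = counts[, 2],
      n_lowneg_nuc = counts[, 3], n_lowneg_cytneg = counts[, 4],
      total_ctc = totals)
  })
}

#' Default cohort-generator settings
#'
#' The defaults mirror the observed cohort structure of the study
#' population: early-disease patients have a low CTC detection rate
#' (about 16%) and CTC pools dominated by the ALDH1-low/neg,
#' TWIST-cytoplasmic/negative phenotype; metastatic patients have a 50%
#' detection rate, larger per-patient CTC burdens, and pools dominated by
#' the ALDH1-high / TWIST-nuclear phenotype.
#'
#' @param setting `"early"` or `"metastatic"`.
#' @return List with `detection_rate`, `phenotype_probs`, `ctc_count_dist`.
#' @export
cohort_defaults <- function(setting = c("early", "metastatic")) {
  setting <- match.arg(setting)
  if (setting == "early") {
    list(detection_rate = 0.163,
         phenotype_probs = c(0.129, 0.258, 0.194, 0.419),
         ctc_count_dist = function(n) 1L + rnbinom(n, size = 1.2, mu = 1.4))
  } else {
    list(detection_rate = 0.50,
         phenotype_probs = c(0.615, 0.220, 0.088, 0.077),
         ctc_count_dist = function(n) 1L + rnbinom(n, size = 0.8, mu = 2.6))
  }
}

#' Synthetic labelled control cells for calibration
#'
#' Emulates the manual calibration of the ALDH1 exposure cut-offs: a panel
#' of control cells is labelled by eye as high-, low- or non-expressing and
#' then measured in exposure units. Each class is built as a balanced
#' multiset on the exposure grid — the class extremes are always present and
#' values are paired symmetrically about the class median — so the observed
#' range and median of each class match the target population exactly for
#' any seed, while the individual draws vary.
#'
#' @param n_per_class Cells per class (default 500).
#' @param ranges Named list of class exposure ranges on the grid.
#' @param medians Named vector of class median exposures.
#' @param step Grid step (default 5).
#' @param seed Integer seed (permutes and samples the filler values).
#' @return Tibble with columns `level` and `exposure`.
#' @export
#' @examples
#' derive_cutoffs(simulate_control_cells(seed = 7))
simulate_control_cells <- function(n_per_class = 500,
                                   ranges = list(high = c(5, 25),
                                                 low = c(30, 55),
                                                 neg = c(60, 90)),
                                   medians = c(high = 15, low = 45, neg = 70),
                                   step = 5, seed = 1L) {
  if (n_per_class < 6) abort("n_per_class must be at least 6")
  out <- purrr::imap(ranges, function(rg, lvl) {
    med <- medians[[lvl]]
    if (med <= rg[1] || med >= rg[2] || med %% step != 0) {
      abort("each class median must be an interior grid value of its range")
    }
    below <- seq(rg[1], med - step, by = step)
    above <- seq(med + step, rg[2], by = step)
    n_mid <- max(2L, 2L * ceiling(n_per_class * 0.1))
    k <- (n_per_class - n_mid) %/% 2L
    n_mid <- n_per_class - 2L * k
    vals <- with_local_seed(derive_seed(seed, "truth", match(lvl, names(ranges))), {
      lo <- c(rg[1], below[sample.int(length(below), k - 1, replace = TRUE)])
      hi <- c(rg[2], above[sample.int(length(above), k - 1, replace = TRUE)])
      all_vals <- c(lo, rep(med, n_mid), hi)
      all_vals[sample.int(length(all_vals))]
    })
    tibble(level = lvl, exposure = vals)
  })
  bind_rows(out)
}
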