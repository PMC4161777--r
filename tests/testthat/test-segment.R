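test_that("blank DAPI channel yields an empty segmentation", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64), min_area = 10)), 0)
  res <- measure_cells(array(0, c(32, 32, 1), dimnames = list(NULL, NULL, "dapi")),
                       matrix(0L, 32, 32), matrix(0L, 32, 32))
  expect_equal(nrow(res), 0)
})

test_that("every synthetic nucleus is found on a non-overlapping lawn", {
  cs <- simulate_cytospin(quick_config(seed = 21, n_pbmc = 120, size = 256))
  nuclei <- segment_nuclei(channel(cs, "dapi"), min_area = 10)
  expect_equal(max(nuclei), 120)
})

test_that("watershed splits a fused nucleus doublet with distinct centres", {
  dapi <- matrix(0, 64, 64)
  dapi <- draw_disc(dapi, 32, 28, 5, 0.8)
  dapi <- draw_disc(dapi, 32, 36, 5, 0.8)   # overlapping discs, two centres
  lab <- segment_nuclei(dapi, min_area = 10)
  expect_equal(max(lab), 2)
})

test_that("cell masks honour containment, disjointness and label matching", {
  for (s in c(2, 13)) {
    spiked <- tibble::tibble(aldh1_level = c("high", "neg"),
                             twist_loc = c("nuc", "cyt"))
    cs <- simulate_cytospin(quick_config(seed = s, n_pbmc = 70, size = 224),
                            spiked)
    nuclei <- segment_nuclei(channel(cs, "dapi"), min_area = 10)
    cells <- segment_cells(channel(cs, "ck"), nuclei)
    # nucleus pixels keep their label inside the cell image
    expect_true(all(cells[nuclei > 0] == nuclei[nuclei > 0]))
    res <- measure_cells(cs, nuclei, cells)
    expect_true(all(res$nucleus_area <= res$cell_area))
    expect_true(all(res$nc_ratio > 0 & res$nc_ratio <= 1))
    expect_equal(nrow(res), max(nuclei))
  }
})

test_that("morphology of constructed discs matches analytic geometry", {
  # nucleus radius 16 inside a cell of radius 20: N:C ratio (16/20)^2
  H <- 64
  nuclei <- disc_label(H, H, 32, 32, 16)
  cells <- disc_label(H, H, 32, 32, 20)
  img <- array(0.5, c(H, H, 1), dimnames = list(NULL, NULL, "x"))
  res <- measure_cells(img, nuclei, cells)
  expect_equal(res$nc_ratio, 0.64, tolerance = 0.02)
  expect_equal(res$cell_area, pi * 20^2, tolerance = 0.02)
  expect_equal(res$equivalent_diameter, 40, tolerance = 0.02)
  expect_false(res$on_border)

  # nucleus filling the whole cell: N:C ratio is exactly 1
  res1 <- measure_cells(img, nuclei, nuclei)
  expect_equal(res1$nc_ratio, 1)
  # cytoplasm mean is undefined (empty mask), flagged as NA not an error
  expect_true(is.na(res1$x_cyt_mean))
})

test_that("rendered tumour cells measure close to their ground truth", {
  spiked <- tibble::tibble(aldh1_level = c("low", "high"),
                           twist_loc = c("nuc", "cyt"))
  cs <- simulate_cytospin(quick_config(seed = 31, n_pbmc = 60, size = 224),
                          spiked)
  nuclei <- segment_nuclei(channel(cs, "dapi"), min_area = 10)
  cells <- segment_cells(channel(cs, "ck"), nuclei)
  res <- measure_cells(cs, nuclei, cells)
  gt <- cs$ground_truth[cs$ground_truth$cell_kind == "tumour", ]
  for (i in seq_len(nrow(gt))) {
    j <- which.min((res$row - gt$row[i])^2 + (res$col - gt$col[i])^2)
    analytic_area <- pi * (gt$diameter[i] / 2)^2
    expect_lt(abs(res$cell_area[j] - analytic_area) / analytic_area, 0.10)
    expect_lt(abs(res$nc_ratio[j] - 0.8), 0.1)
  }
})

test_that("cells clipped at the image border keep their invariants", {
  cfg <- quick_config(seed = 1, n_pbmc = 0, size = 128)
  cs <- simulate_cytospin(cfg, tibble::tibble(
    aldh1_level = "high", twist_loc = "nuc", row = 12, col = 64))
  nuclei <- segment_nuclei(channel(cs, "dapi"), min_area = 10)
  # shift the rendered nucleus mask against the border by cropping the image
  dapi <- channel(cs, "dapi")[6:128, , drop = FALSE]
  ck <- channel(cs, "ck")[6:128, , drop = FALSE]
  nuclei2 <- segment_nuclei(dapi, min_area = 10)
  cells2 <- segment_cells(ck, nuclei2)
  img <- array(c(dapi, ck), c(nrow(dapi), ncol(dapi), 2),
               dimnames = list(NULL, NULL, c("dapi", "ck")))
  res <- measure_cells(img, nuclei2, cells2)
  expect_equal(nrow(res), 1)
  expect_true(res$on_border)
  expect_true(res$nucleus_area <= res$cell_area)
  expect_true(res$nc_ratio <= 1)
})

test_that("CK threshold sits well above background on rare-cell images", {
  cs <- simulate_cytospin(quick_config(seed = 8, n_pbmc = 80, size = 224),
                          tibble::tibble(aldh1_level = "high",
                                         twist_loc = "nuc"))
  nuclei <- segment_nuclei(channel(cs, "dapi"), min_area = 10)
  th <- ck_threshold(channel(cs, "ck"), nuclei)
  bg <- channel(cs, "ck")[nuclei == 0]
  expect_gt(th, quantile(bg, 0.99))
  expect_lt(th, 0.5)  # still far below the rendered CK signal
})
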