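# Independent oracles, deliberately written from first principles and kept
# free of the package's own code paths.

# Yates-corrected chi-square on a 2x2 table: direct formula evaluation.
yates_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(pmax(0, abs(tab - E) - 0.5)^2 / E)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (untied samples, small n). U counts pairs with a > b.
mw_exact_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  u_obs <- sum(outer(a, b, ">"))
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) sum(i) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small, fast simulation configuration shared by image-based tests.
quick_config <- function(seed, n_pbmc = 120, size = 256, ...) {
  sim_config(n_pbmc = n_pbmc, image_size = c(size, size), seed = seed, ...)
}

# Draw a filled disc (flat intensity) on a matrix; pixel-centre sampling,
# matching the simulator's rendering convention.
draw_disc <- function(m, cr, cc, radius, value) {
  d2 <- outer((seq_len(nrow(m)) - cr)^2, (seq_len(ncol(m)) - cc)^2, "+")
  m[d2 <= radius^2] <- value
  m
}

disc_label <- function(H, W, cr, cc, radius, label = 1L) {
  m <- matrix(0L, H, W)
  d2 <- outer((seq_len(H) - cr)^2, (seq_len(W) - cc)^2, "+")
  m[d2 <= radius^2] <- label
  m
}

# Match called CTCs to ground-truth tumour cells by centroid distance.
match_ctcs <- function(result, truth, max_dist = 5) {
  ctc <- result[result$is_ctc, , drop = FALSE]
  tum <- truth[truth$cell_kind == "tumour", , drop = FALSE]
  hits <- integer(0)
  for (i in seq_len(nrow(tum))) {
    d <- sqrt((ctc$row - tum$row[i])^2 + (ctc$col - tum$col[i])^2)
    hits[i] <- if (length(d) && min(d) < max_dist) which.min(d) else NA_integer_
  }
  list(ctc = ctc, tumour = tum, match = hits)
}

table4_counts <- function() {
  # Per-patient CTC phenotype counts of the index patients, in the order
  # (high_nuc, high_cytneg, lowneg_nuc, lowneg_cytneg).
  list(
    early = list(p1 = c(0, 0, 0, 3), p2 = c(0, 0, 0, 5), p3 = c(1, 0, 2, 0),
                 p4 = c(3, 1, 2, 0), p5 = c(0, 6, 0, 0)),
    metastatic = list(p1 = c(2, 0, 0, 0), p2 = c(10, 1, 0, 0),
                      p3 = c(1, 0, 1, 0), p4 = c(1, 2, 0, 0),
                      p5 = c(5, 14, 0, 2), p6 = c(0, 0, 0, 2),
                      p7 = c(3, 2, 6, 0))
  )
}
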