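# Independent voxel-by-voxel oracle for the quantification formulas,
# deliberately loop-based and kept separate from the package's vectorized
# implementation.

naive_quant <- function(intens, labels, spacing, threshold = 200) {
  n_mask <- 0L
  n_le_thr <- 0L
  n_le_1000 <- 0L
  s <- 0
  for (i in seq_len(nrow(labels))) {
    for (j in seq_len(ncol(labels))) {
      if (labels[i, j] > 0L) {
        n_mask <- n_mask + 1L
        v <- intens[i, j]
        s <- s + v
        if (v <= threshold) n_le_thr <- n_le_thr + 1L
        if (v <= 1000) n_le_1000 <- n_le_1000 + 1L
      }
    }
  }
  csa_total <- n_mask * spacing^2
  list(
    csa_total = csa_total,
    csa_fatfree = if (n_mask > 0) csa_total * n_le_thr / n_le_1000 else 0,
    pdff_muscle = if (n_mask > 0) s / n_mask / 10 else NA_real_
  )
}

# random small test grid with at least one mask voxel
random_grid <- function(max_side = 20) {
  nr <- sample(3:max_side, 1)
  nc <- sample(3:max_side, 1)
  labels <- matrix(sample(0:8, nr * nc, replace = TRUE,
                          prob = c(0.5, rep(0.0625, 8))),
                   nr, nc)
  if (all(labels == 0L)) labels[1, 1] <- 1L
  intens <- matrix(runif(nr * nc, 0, 1000), nr, nc)
  spacing <- sample(c(0.8, 1, 1.5, 2), 1)
  list(
    labels = labels,
    intens = intens,
    spacing = spacing,
    map = pdff_map(intens, pixel_spacing = spacing),
    masks = compartment_masks(labels, check_connected = FALSE)
  )
}

# small, fast generator configuration for tests that do not need the full
# study-sized grid
small_config <- function(n_subjects = 8, seed = 1, grid_size = 96,
                         pixel_spacing = 3, ...) {
  generator_config(n_subjects = n_subjects, seed = seed,
                   grid_size = grid_size, pixel_spacing = pixel_spacing, ...)
}
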