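# Fixture builders and independent oracles used across the suite.

SP_DEFAULT <- c(0.82, 0.69, 0.69)

# rasterise an axis-aligned or oblique tube (flat caps) into a logical array
tube_mask <- function(dim_zyx, spacing, p1, p2, r) {
  array(gland3d:::cpp_rasterize_tubes(as.integer(dim_zyx), spacing,
                                      matrix(c(p1, p2, r), 1), logical(0)),
        dim = dim_zyx)
}

ball_mask <- function(dim_zyx, spacing, center, r) {
  array(gland3d:::cpp_rasterize_balls(as.integer(dim_zyx), spacing,
                                      matrix(c(center, r), 1), logical(0)),
        dim = dim_zyx)
}

# independent brute-force Euclidean distance oracle: for every voxel centre,
# the minimum distance to any foreground voxel centre (physical units)
brute_force_edt <- function(mask, spacing) {
  dm <- dim(mask)
  fg <- which(mask)
  stopifnot(length(fg) > 0)
  fz <- arrayInd(fg, dm)
  P <- cbind((fz[, 1] - 1) * spacing[1], (fz[, 2] - 1) * spacing[2],
             (fz[, 3] - 1) * spacing[3])
  all_idx <- arrayInd(seq_len(prod(dm)), dm)
  A <- cbind((all_idx[, 1] - 1) * spacing[1], (all_idx[, 2] - 1) * spacing[2],
             (all_idx[, 3] - 1) * spacing[3])
  out <- numeric(nrow(A))
  chunk <- 2048L
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ac <- A[s:e, , drop = FALSE]
    d2 <- outer(Ac[, 1], P[, 1], `-`)^2 + outer(Ac[, 2], P[, 2], `-`)^2 +
      outer(Ac[, 3], P[, 3], `-`)^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  array(out, dim = dm)
}

# standard phantom used by several end-to-end tests
demo_phantom <- function(seed = 9, n_macrophage = 60, n_beta = 150,
                         prolif = 0.2, target_fraction = 0.02) {
  spec <- phantom_spec(
    shape = c(64, 128, 128), spacing_um = SP_DEFAULT,
    vessels = list(target_fraction = target_fraction,
                   radius_um = c(2.2, 3.5), segment_length_um = 50),
    cell_populations = list(
      list(name = "macrophage", markers = "CD68", n = n_macrophage,
           distance_um = c(0, 18)),
      list(name = "beta", markers = "CXCR4", n = n_beta,
           proliferating_fraction = prolif)),
    seed = seed)
  generate_phantom(spec)
}

# cells segmented and phenotyped from a demo phantom
demo_cells <- function(ph, markers = c("CD68", "CXCR4", "Ki67")) {
  sp <- ph$grid$spacing_um
  markers <- intersect(markers, ph$grid$channel_names)
  mk <- lapply(markers, function(m) get_channel(ph$grid, m))
  names(mk) <- markers
  segment_cells(get_channel(ph$grid, "nuclei"), sp, marker_channels = mk)
}
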