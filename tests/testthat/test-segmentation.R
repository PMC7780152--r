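test_that("background subtraction removes flat fields and ramps, keeps tubes", {
  dm <- c(32L, 64L, 64L)
  sp <- c(1, 1, 1)
  flat <- array(37, dim = dm)
  out <- subtract_background(flat, sp, 20)
  expect_lt(max(abs(out)), 1e-6)
  # bright tube on a linear ramp
  ramp <- array(rep(seq(0, 100, length.out = dm[2]), each = dm[1]), dim = dm)
  tube <- tube_mask(dm, sp, c(16, 5, 32), c(16, 59, 32), 3)
  img <- ramp + 150 * tube
  out <- subtract_background(img, sp, 20)
  in_tube <- mean(out[tube])
  off_tube <- out[!tube & ramp > 50]
  expect_gt(in_tube, 0.9 * 150 * mean(!tube))  # contrast preserved
  expect_lt(mean(off_tube), 0.1 * mean(ramp))  # ramp suppressed > 90%
  expect_error(subtract_background(img, sp, 0), "scale_um")
})

test_that("surface segmentation recovers a cylinder within 5% volume", {
  dm <- c(122L, 145L, 145L)
  sp <- SP_DEFAULT
  spec <- phantom_spec(shape = dm, spacing_um = sp,
                       vessels = list(list(p1 = c(50, 10, 50),
                                           p2 = c(50, 90, 50), radius_um = 5)),
                       seed = 1)
  ph <- generate_phantom(spec)
  cs <- segment_surface(get_channel(ph$grid, "Emcn"), sp,
                        smooth_sigma_um = 0.5, threshold = (200 + 10) / 2)
  expect_identical(nrow(cs$components), 1L)
  expect_equal(cs$components$volume_um3, pi * 25 * 80, tolerance = 0.05)
  jac <- sum(cs$mask & ph$truth$vessel_mask) / sum(cs$mask | ph$truth$vessel_mask)
  expect_gte(jac, 0.95)
})

test_that("surface segmentation handles empty and invalid channels", {
  dm <- c(8L, 16L, 16L)
  cs <- segment_surface(array(0, dim = dm), c(1, 1, 1), 0, threshold = 0.5)
  expect_identical(nrow(cs$components), 0L)
  bad <- array(0, dim = dm); bad[1] <- NaN
  expect_error(segment_surface(bad, c(1, 1, 1)), "NA")
})

test_that("connectivity merges components joined by a bridge", {
  dm <- c(32L, 64L, 32L)
  sp <- c(1, 1, 1)
  two <- ball_mask(dm, sp, c(16, 15, 16), 6) |
    ball_mask(dm, sp, c(16, 45, 16), 6)
  cs <- component_set(two, sp)
  expect_identical(nrow(cs$components), 2L)
  bridged <- two | tube_mask(dm, sp, c(16, 15, 16), c(16, 45, 16), 2)
  expect_identical(nrow(component_set(bridged, sp)$components), 1L)
  expect_equal(sum(cs$components$voxel_count), sum(two))
})

test_that("sphericity is near 1 for balls and decreases with elongation", {
  sp <- c(1, 1, 1)
  ball <- ball_mask(c(24L, 24L, 24L), sp, c(11.5, 11.5, 11.5), 8)
  psi_ball <- component_set(ball, sp)$components$sphericity
  expect_gte(psi_ball, 0.9)
  expect_lte(psi_ball, 1.05)
  # cylinders of fixed volume, increasing length: psi strictly decreases
  vol <- pi * 6^2 * 24
  psis <- vapply(c(24, 48, 96), function(L) {
    r <- sqrt(vol / (pi * L))
    dmL <- c(40L, as.integer(L + 20), 40L)
    m <- tube_mask(dmL, sp, c(20, 10, 20), c(20, 10 + L, 20), r)
    component_set(m, sp)$components$sphericity
  }, numeric(1))
  expect_true(all(diff(psis) < 0))
  expect_lt(psis[3], psi_ball)
})

test_that("noise filter removes small high-sphericity blobs, keeps tubes", {
  dm <- c(48L, 96L, 96L)
  sp <- c(1, 1, 1)
  tube <- tube_mask(dm, sp, c(24, 5, 48), c(24, 90, 48), 4)
  blobs <- ball_mask(dm, sp, c(10, 20, 20), 3) |
    ball_mask(dm, sp, c(38, 70, 70), 3.5)
  cs <- component_set(tube | blobs, sp)
  expect_identical(nrow(cs$components), 3L)
  kept <- filter_noise_components(cs, max_volume_um3 = 500, min_sphericity = 0.8)
  expect_identical(nrow(kept$components), 1L)
  expect_gt(kept$components$elongation, 3)
  # a large ball above the size guard is retained
  big <- ball_mask(dm, sp, c(24, 48, 48), 10)
  kept2 <- filter_noise_components(component_set(big, sp), 500, 0.8)
  expect_identical(nrow(kept2$components), 1L)
  # empty set passes through
  empty <- component_set(array(FALSE, dim = c(4L, 4L, 4L)), sp)
  expect_identical(nrow(filter_noise_components(empty, 500, 0.8)$components), 0L)
})

test_that("cell segmentation finds well-separated planted nuclei exactly", {
  spec <- phantom_spec(shape = c(40, 80, 80), spacing_um = SP_DEFAULT,
                       vessels = list(list(p1 = c(16, 5, 27),
                                           p2 = c(16, 50, 27), radius_um = 2.5)),
                       cell_populations = list(
                         list(name = "cell", markers = "CD68", n = 2,
                              distance_um = c(5, 15))),
                       seed = 2)
  ph <- generate_phantom(spec)
  cells <- demo_cells(ph, "CD68")
  expect_identical(nrow(cells), 2L)
  tr <- ph$truth$cells
  for (i in seq_len(2)) {
    d <- sqrt((cells$z_um - tr$z_um[i])^2 + (cells$y_um - tr$y_um[i])^2 +
                (cells$x_um - tr$x_um[i])^2)
    expect_lte(min(d), sqrt(sum(SP_DEFAULT^2))) # within one voxel diagonal
  }
})

test_that("cell segmentation count equals planted count at 100 nuclei", {
  ph <- demo_phantom(seed = 17, n_macrophage = 40, n_beta = 60, prolif = 0)
  cells <- demo_cells(ph)
  expect_identical(nrow(cells), 100L)
})

test_that("an empty nuclei channel yields an empty cell table with a warning", {
  expect_warning(
    cells <- segment_cells(array(0, dim = c(8L, 16L, 16L)), c(1, 1, 1)),
    "no nuclei")
  expect_identical(nrow(cells), 0L)
})

test_that("phenotype bands follow the inclusive boundary convention", {
  cells <- data.frame(id = 1:4,
                      mean_CD31 = c(10, 10, 2, 0),
                      mean_Emcn = c(30, 12, 30, 0))
  thr <- list(CD31 = c(t_pos = 10, t_hi = 20), Emcn = c(t_pos = 10, t_hi = 30))
  rules <- list(phenotype_rule("CD31+Emcn-hi", CD31 = "pos", Emcn = "hi"),
                phenotype_rule("CD31+Emcn-lo", CD31 = "pos", Emcn = "lo"))
  out <- classify_phenotypes(cells, rules, thr)
  # exactly at t_pos counts as pos; exactly at t_hi counts as hi
  expect_identical(out$phenotype,
                   c("CD31+Emcn-hi", "CD31+Emcn-lo", "unclassified", "unclassified"))
  expect_error(classify_phenotypes(cells, list(phenotype_rule("x", VEGFA = "pos"))),
               "unknown marker")
})

test_that("priority order decides overlapping phenotype rules", {
  cells <- data.frame(id = 1, mean_A = 100)
  thr <- list(A = c(t_pos = 10, t_hi = 50))
  out <- classify_phenotypes(cells,
                             list(phenotype_rule("first", A = "hi"),
                                  phenotype_rule("second", A = "pos")), thr)
  expect_identical(out$phenotype, "first")
})
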