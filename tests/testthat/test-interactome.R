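test_that("distance field equals the brute-force oracle on random masks", {
  set.seed(11)
  for (rep in 1:5) {
    dm <- as.integer(sample(12:20, 3, replace = TRUE))
    sp <- runif(3, 0.5, 2)
    mask <- array(runif(prod(dm)) < 0.06, dim = dm)
    if (!any(mask)) mask[1] <- TRUE
    field <- distance_to_vessels(mask, sp)
    expect_lt(max(abs(unclass(field) - brute_force_edt(mask, sp))), 1e-9)
    expect_true(all(unclass(field)[mask] == 0))
  }
})

test_that("anisotropic spacing is honoured exactly", {
  dm <- c(5L, 5L, 5L)
  mask <- array(FALSE, dim = dm)
  mask[3, 3, 3] <- TRUE
  f <- distance_to_vessels(mask, c(2, 1, 1))
  expect_equal(unclass(f)[4, 3, 3], 2) # one step along z
  expect_equal(unclass(f)[3, 4, 3], 1)
  expect_equal(unclass(f)[3, 3, 5], 2)
})

test_that("an empty vessel mask yields an infinite field with a warning", {
  expect_warning(f <- distance_to_vessels(array(FALSE, dim = c(4L, 4L, 4L)),
                                          c(1, 1, 1)), "empty")
  expect_true(all(is.infinite(unclass(f))))
})

test_that("cell distances interpolate the field at centroids", {
  dm <- c(24L, 48L, 48L)
  sp <- SP_DEFAULT
  vm <- tube_mask(dm, sp, c(10, 3, 16), c(10, 28, 16), 2.5)
  field <- distance_to_vessels(vm, sp)
  # a cell sitting on a vessel voxel has distance 0
  idx <- which(vm)[10]
  zyx <- arrayInd(idx, dm)
  cells <- data.frame(id = 1L, z_um = (zyx[1] - 1) * sp[1],
                      y_um = (zyx[2] - 1) * sp[2], x_um = (zyx[3] - 1) * sp[3])
  expect_equal(annotate_cell_distances(cells, field)$distance_to_vessel_um, 0)
  # planted band [10, 12]: annotated within one voxel diagonal of the band
  pts <- place_cells_at_distance(vm, sp, 15, 10, 12, seed = 2)
  cells2 <- data.frame(id = 1:15, z_um = pts[, 1], y_um = pts[, 2],
                       x_um = pts[, 3])
  d <- annotate_cell_distances(cells2, field)$distance_to_vessel_um
  delta <- sqrt(sum(sp^2))
  expect_true(all(d >= 10 - delta & d <= 12 + delta))
  # empty table passes through; out-of-grid centroid errors
  empty <- annotate_cell_distances(cells2[0, ], field)
  expect_identical(nrow(empty), 0L)
  bad <- data.frame(id = 1L, z_um = 1e5, y_um = 0, x_um = 0)
  expect_error(annotate_cell_distances(bad, field), "outside")
})

test_that("the proximity rule is inclusive at the 18 um boundary", {
  cells <- data.frame(id = 1:4,
                      distance_to_vessel_um = c(0, 17.9, 18.0, 18.01))
  out <- interactome_membership(cells, 18)
  expect_identical(out$member, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(interactome_membership(data.frame(id = 1)), "not annotated")
  # membership count is monotone in the threshold
  set.seed(3)
  d <- data.frame(id = 1:50, distance_to_vessel_um = runif(50, 0, 40))
  counts <- vapply(seq(0, 40, by = 2.5),
                   function(th) sum(interactome_membership(d, th)$member),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("interaction matrices count per subset and cell type", {
  dm <- c(24L, 48L, 48L)
  sp <- c(1, 1, 1)
  vm <- tube_mask(dm, sp, c(12, 4, 24), c(12, 44, 24), 3)
  surf <- place_cells_at_distance(vm, sp, 10, 0, 0, seed = 5)
  cells <- data.frame(id = 1:10, type = "pericyte",
                      z_um = surf[, 1], y_um = surf[, 2], x_um = surf[, 3])
  m <- build_interactome(cells, list(vessels = vm), sp)
  expect_identical(m$n_within, 10L)
  expect_identical(m$n_total, 10L)
  expect_equal(m$fraction, 1)
  expect_true(m$present)
  # empty subset omitted with a warning
  expect_warning(
    m2 <- build_interactome(cells, list(vessels = vm,
                                        none = array(FALSE, dim = dm)), sp),
    "empty")
  expect_identical(unique(m2$subset), "vessels")
  # absent cell type gives a flagged zero row
  cells$type <- as.character(cells$type)
  m3 <- build_interactome(cells[0, ], list(vessels = vm), sp)
  expect_identical(nrow(m3), 0L)
})

test_that("interactome fractions survive volume padding and relabeling", {
  ph <- demo_phantom(seed = 19, n_macrophage = 30, n_beta = 30)
  sp <- ph$grid$spacing_um
  cells <- ph$truth$cells
  m1 <- build_interactome(cells, list(v = ph$truth$vessel_mask), sp)
  dmp <- dim(ph$truth$vessel_mask) + c(6L, 6L, 6L)
  padded <- array(FALSE, dim = dmp)
  padded[1:dim(ph$truth$vessel_mask)[1], 1:dim(ph$truth$vessel_mask)[2],
         1:dim(ph$truth$vessel_mask)[3]] <- ph$truth$vessel_mask
  m2 <- build_interactome(cells, list(v = padded), sp)
  expect_equal(m1$fraction, m2$fraction)
})

test_that("differential interactome reports gained, lost and stable calls", {
  base <- data.frame(subset = "v", cell_type = c("pericyte", "decorin"),
                     n_within = c(9L, 0L), n_total = c(10L, 10L),
                     fraction = c(0.9, 0), present = c(TRUE, FALSE),
                     undefined = FALSE)
  mk <- function(df) {
    attr(df, "max_distance_um") <- 18
    class(df) <- c("interaction_matrix", "data.frame")
    df
  }
  young <- mk(base)
  aged <- mk(transform(base, n_within = c(9L, 8L), fraction = c(0.9, 0.8),
                       present = c(TRUE, TRUE)))
  d <- differential_interactome(young, aged)
  expect_identical(d$status[d$cell_type == "decorin"], "gained")
  expect_identical(d$status[d$cell_type == "pericyte"], "stable")
  expect_identical(differential_interactome(young, young)$status,
                   c("stable", "stable"))
  lost <- differential_interactome(aged, young)
  expect_identical(lost$status[lost$cell_type == "decorin"], "lost")
  other <- mk(transform(base, cell_type = c("x", "y")))
  expect_error(differential_interactome(young, other), "vocabular")
})
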