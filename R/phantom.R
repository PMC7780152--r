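# Synthetic gland phantoms -----------------------------------------------------
#
# The generator emulates the statistical structure the analysis assumes:
# tubular capillary networks at a controlled volume fraction, thicker
# alpha-SMA+ artery tubes, dense capillary plexi inside insulin+ islet
# spheroids, nuclei blobs, and cell populations placed at controlled
# distances from the vessel surface, all rendered as marker channels with an
# optional Gaussian PSF and additive Gaussian noise. Every phantom carries
# full ground truth (masks, true cell table, true scalar metrics).

#' Specification of a synthetic gland phantom
#'
#' @param shape integer `(Z, Y, X)` voxel counts.
#' @param spacing_um voxel pitch `(dz, dy, dx)` in micrometres.
#' @param vessels either a list of explicit tube segments (each
#'   `list(p1 =, p2 =, radius_um =)` with endpoints in micrometres, axis
#'   order z, y, x) or a random-network spec
#'   `list(target_fraction =, radius_um = c(lo, hi), segment_length_um =)`;
#'   random segments are added until the rasterised vessel volume fraction
#'   reaches `target_fraction`.
#' @param arteries list of explicit thick tube segments (same form as
#'   `vessels`), rendered on the alpha-SMA channel. Arteries are vessels too:
#'   their voxels join the vessel mask.
#' @param islets list of `list(center =, radius_um =, insulin_fraction =,
#'   plexus = list(n_segments =, radius_um =))`; the insulin+ core is a
#'   concentric ball of volume fraction `insulin_fraction` (default 1) so the
#'   true area fraction is analytic; the plexus adds random capillaries
#'   through the islet interior.
#' @param cell_populations list of
#'   `list(name =, markers =, n =, distance_um = c(d_min, d_max) | NULL,
#'   region = "tissue" | "islet", proliferating_fraction = 0)`. A distance
#'   band places centroids with exact distance-to-vessel inside the band;
#'   `NULL` places them uniformly in the stated region.
#' @param fg,bg foreground/background mean intensity per marker channel.
#' @param noise_sd additive Gaussian noise sd (clipped at zero).
#' @param psf_sigma_um isotropic Gaussian PSF sigma in micrometres (0 = none).
#' @param nucleus_sigma_um nuclei are rendered as Gaussian blobs of this
#'   sigma (default 2 um).
#' @param cell_radius_um radius of the cytoplasmic marker ball per cell.
#' @param min_cell_separation_um minimum distance between any two placed
#'   cell centroids (default 8 um = 4 nucleus sigmas, so nuclei are
#'   resolvable by blob detection).
#' @param seed integer seed; identical (spec, seed) gives identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 128, 128),
                         spacing_um = c(0.82, 0.69, 0.69),
                         vessels = list(target_fraction = 0.02,
                                        radius_um = c(2.5, 4),
                                        segment_length_um = 60),
                         arteries = list(),
                         islets = list(),
                         cell_populations = list(),
                         fg = 200, bg = 10,
                         noise_sd = 0, psf_sigma_um = 0,
                         nucleus_sigma_um = 2, cell_radius_um = 3.5,
                         min_cell_separation_um = 8,
                         seed = 1L) {
  shape <- as.integer(unlist(shape))
  spacing_um <- as.numeric(unlist(spacing_um))
  stopifnot(length(shape) == 3L, all(shape >= 4),
            length(spacing_um) == 3L, all(spacing_um > 0),
            noise_sd >= 0, psf_sigma_um >= 0, fg > bg, bg >= 0)
  # coerce nested fields (lists when deserialised from YAML/JSON)
  norm_seg <- function(s) {
    if (!is.list(s)) return(s)
    if (!is.null(s$p1)) s$p1 <- as.numeric(unlist(s$p1))
    if (!is.null(s$p2)) s$p2 <- as.numeric(unlist(s$p2))
    if (!is.null(s$radius_um)) s$radius_um <- as.numeric(s$radius_um)
    s
  }
  explicit <- length(vessels) && all(vapply(vessels, is.list, TRUE))
  if (explicit) vessels <- lapply(vessels, norm_seg)
  else {
    if (!is.null(vessels$radius_um))
      vessels$radius_um <- as.numeric(unlist(vessels$radius_um))
  }
  arteries <- lapply(arteries, norm_seg)
  islets <- lapply(islets, function(i) {
    i$center <- as.numeric(unlist(i$center))
    i$radius_um <- as.numeric(i$radius_um)
    if (!is.null(i$insulin_fraction)) i$insulin_fraction <- as.numeric(i$insulin_fraction)
    i
  })
  cell_populations <- lapply(cell_populations, function(p) {
    if (is.null(p[["n"]])) {
      if (!is.null(p[["count"]])) p[["n"]] <- p[["count"]]
      else if (!is.null(p[["FALSE"]])) p[["n"]] <- p[["FALSE"]] # YAML 1.1 reads bare `n:` as a boolean key
    }
    stopifnot(!is.null(p$name), !is.null(p[["n"]]))
    p$name <- as.character(p$name)
    p$markers <- as.character(unlist(p$markers))
    p[["n"]] <- as.integer(p[["n"]])
    if (!is.null(p$distance_um)) p$distance_um <- as.numeric(unlist(p$distance_um))
    if (!is.null(p$proliferating_fraction))
      p$proliferating_fraction <- as.numeric(p$proliferating_fraction)
    p
  })
  for (p in cell_populations) {
    stopifnot(p$n >= 0)
    pf <- if (is.null(p$proliferating_fraction)) 0 else p$proliferating_fraction
    stopifnot(pf >= 0, pf <= 1)
    if (!is.null(p$distance_um))
      stopifnot(length(p$distance_um) == 2L, p$distance_um[1] <= p$distance_um[2])
  }
  half_extent <- min(shape * spacing_um) / 2
  for (s in c(if (explicit) vessels else list(), arteries))
    if (!is.null(s$radius_um)) stopifnot(s$radius_um > 0, s$radius_um < half_extent)
  structure(list(shape = as.integer(shape), spacing_um = as.numeric(spacing_um),
                 vessels = vessels, arteries = arteries, islets = islets,
                 cell_populations = cell_populations,
                 fg = fg, bg = bg, noise_sd = noise_sd,
                 psf_sigma_um = psf_sigma_um,
                 nucleus_sigma_um = nucleus_sigma_um,
                 cell_radius_um = cell_radius_um,
                 min_cell_separation_um = min_cell_separation_um,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

seg_matrix <- function(segs) {
  if (!length(segs)) return(matrix(0, 0, 7))
  t(vapply(segs, function(s) c(s$p1, s$p2, s$radius_um), numeric(7)))
}

# random segment with its midpoint inside the box, direction uniform on the
# sphere, clipped endpoints allowed to leave the box (the rasteriser clips)
random_segment <- function(extent, length_um, radius_um) {
  mid <- runif(3, 0.1, 0.9) * extent
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  list(p1 = mid - u * length_um / 2, p2 = mid + u * length_um / 2,
       radius_um = radius_um)
}

#' Generate a synthetic gland phantom with ground truth
#'
#' Renders marker channels (vessel marker `Emcn`, artery marker `aSMA`,
#' islet marker `insulin`, one channel per cell-population marker, `Ki67`
#' for proliferating nuclei, and `nuclei`) and returns the volume together
#' with ground-truth masks, the true cell table and true scalar metrics.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `grid` (a [voxel_grid()]) and `truth` (list:
#'   `vessel_mask`, `artery_mask`, `islet_labels`, `cells` data.frame,
#'   `metrics` list, `segments`, `artery_segments`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$shape
  sp <- spec$spacing_um
  extent <- dm * sp
  nvox <- prod(dm)
  vx <- voxel_volume_um3(sp)

  # --- vessel geometry ---------------------------------------------------
  explicit <- length(spec$vessels) && all(vapply(spec$vessels, is.list, TRUE))
  segs <- if (explicit) spec$vessels else list()
  vessel_mask <- array(cpp_rasterize_tubes(dm, sp, seg_matrix(segs), logical(0)), dim = dm)
  if (!explicit && !is.null(spec$vessels$target_fraction)) {
    vs <- spec$vessels
    len <- if (is.null(vs$segment_length_um)) 60 else vs$segment_length_um
    rr <- if (is.null(vs$radius_um)) c(2.5, 4) else vs$radius_um
    vol_box <- prod(extent)
    iter <- 0L
    while (mean(vessel_mask) < vs$target_fraction && iter < 10000L) {
      iter <- iter + 1L
      r <- runif(1, rr[1], max(rr))
      # final fill: aim the last segment's volume at the remaining deficit,
      # keeping length >= 12 r (stays clearly tubular, well below the
      # sphericity noise cut) and the segment fully inside the box
      need_um3 <- (vs$target_fraction - mean(vessel_mask)) * vol_box
      l_seg <- need_um3 / (pi * r^2)
      if (l_seg < 12 * r) {
        r <- (need_um3 / (12 * pi))^(1 / 3)
        if (r < 1.5 * min(sp)) break # residual deficit is negligible
        l_seg <- 12 * r
      }
      l_seg <- min(len, l_seg)
      for (try in 1:20) {
        s <- random_segment(extent, l_seg, r)
        if (all(s$p1 >= 0 & s$p1 <= extent & s$p2 >= 0 & s$p2 <= extent)) break
      }
      segs <- c(segs, list(s))
      vessel_mask <- array(cpp_rasterize_tubes(dm, sp, seg_matrix(list(s)),
                                               as.logical(vessel_mask)), dim = dm)
    }
  }

  # islet plexus capillaries (confined near the islet centre)
  islet_labels <- array(0L, dim = dm)
  insulin_mask <- array(FALSE, dim = dm)
  for (ii in seq_along(spec$islets)) {
    isl <- spec$islets[[ii]]
    ball <- array(cpp_rasterize_balls(dm, sp,
                    matrix(c(isl$center, isl$radius_um), 1), logical(0)), dim = dm)
    islet_labels[ball] <- ii
    f_ins <- if (is.null(isl$insulin_fraction)) 1 else isl$insulin_fraction
    r_ins <- isl$radius_um * f_ins^(1 / 3)
    insulin_mask <- insulin_mask | array(cpp_rasterize_balls(dm, sp,
                      matrix(c(isl$center, r_ins), 1), logical(0)), dim = dm)
    if (!is.null(isl$plexus) && isl$plexus$n_segments > 0) {
      for (q in seq_len(isl$plexus$n_segments)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        mid <- isl$center + runif(3, -0.4, 0.4) * isl$radius_um
        half <- 0.8 * isl$radius_um
        s <- list(p1 = mid - u * half, p2 = mid + u * half,
                  radius_um = isl$plexus$radius_um)
        segs <- c(segs, list(s))
        vessel_mask <- array(cpp_rasterize_tubes(dm, sp, seg_matrix(list(s)),
                                                 as.logical(vessel_mask)), dim = dm)
      }
    }
  }

  artery_mask <- array(cpp_rasterize_tubes(dm, sp, seg_matrix(spec$arteries),
                                           logical(0)), dim = dm)
  vessel_mask <- vessel_mask | artery_mask

  # --- cells ---------------------------------------------------------------
  dist_field <- NULL
  cells <- list()
  placed <- matrix(numeric(0), 0, 3)
  next_id <- 1L
  # keep cells a nucleus diameter clear of the section borders: nuclei cut by
  # the volume boundary are not analysable and would bias blob detection
  margin_vox <- pmin(ceiling(2 * spec$nucleus_sigma_um / sp),
                     floor((dm - 1) / 2))
  interior <- array(FALSE, dim = dm)
  interior[(1 + margin_vox[1]):(dm[1] - margin_vox[1]),
           (1 + margin_vox[2]):(dm[2] - margin_vox[2]),
           (1 + margin_vox[3]):(dm[3] - margin_vox[3])] <- TRUE
  interior_idx <- which(interior)
  for (p in spec$cell_populations) {
    if (p$n == 0) next
    reg <- if (is.null(p$region)) "tissue" else p$region
    if (!is.null(p$distance_um)) {
      if (is.null(dist_field)) {
        if (!any(vessel_mask)) stop("distance-law placement needs a vessel network")
        dist_field <- array(cpp_edt(as.logical(vessel_mask), dm, sp), dim = dm)
      }
      cand <- which(dist_field >= p$distance_um[1] & dist_field <= p$distance_um[2] &
                      !vessel_mask)
      if (p$distance_um[2] == 0) { # on the vessel surface itself
        bg_edt <- array(cpp_edt(!as.logical(vessel_mask), dm, sp), dim = dm)
        cand <- which(vessel_mask & bg_edt <= min(sp) + 1e-9)
      }
      dvals <- dist_field[cand]
    } else {
      cand <- if (reg == "islet") which(islet_labels > 0) else seq_len(nvox)
      dvals <- NULL
    }
    keep_in <- interior[cand]
    cand <- cand[keep_in]
    if (!is.null(dvals)) dvals <- dvals[keep_in]
    if (length(cand) < p$n)
      stop(sprintf("population '%s': only %d voxels satisfy the placement law (need %d)",
                   p$name, length(cand), p$n))
    # greedy placement with minimum separation so nuclei remain resolvable
    shuffled <- sample(cand)
    pick <- integer(0)
    for (v in shuffled) {
      if (length(pick) >= p$n) break
      zyx_v <- arrayInd(v, dm)
      pos_v <- (zyx_v - 1) * sp
      if (length(placed)) {
        d2 <- (placed[, 1] - pos_v[1])^2 + (placed[, 2] - pos_v[2])^2 +
          (placed[, 3] - pos_v[3])^2
        if (min(d2) < spec$min_cell_separation_um^2) next
      }
      pick <- c(pick, v)
      placed <- rbind(placed, pos_v)
    }
    if (length(pick) < p$n)
      stop(sprintf("population '%s': could not place %d cells with %g um separation",
                   p$name, p$n, spec$min_cell_separation_um))
    zyx <- arrayInd(pick, dm)
    pf <- if (is.null(p$proliferating_fraction)) 0 else p$proliferating_fraction
    nprol <- round(p$n * pf)
    prol <- rep(FALSE, p$n)
    if (nprol > 0) prol[sample.int(p$n, nprol)] <- TRUE
    cells[[length(cells) + 1L]] <- data.frame(
      id = seq.int(next_id, next_id + p$n - 1L),
      type = p$name,
      z_um = (zyx[, 1] - 1) * sp[1],
      y_um = (zyx[, 2] - 1) * sp[2],
      x_um = (zyx[, 3] - 1) * sp[3],
      true_distance_um = if (is.null(dvals)) NA_real_ else dvals[match(pick, cand)],
      proliferating = prol,
      islet = islet_labels[pick],
      stringsAsFactors = FALSE)
    next_id <- next_id + p$n
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(id = integer(), type = character(), z_um = numeric(),
               y_um = numeric(), x_um = numeric(), true_distance_um = numeric(),
               proliferating = logical(), islet = integer(),
               stringsAsFactors = FALSE)

  # --- channels -------------------------------------------------------------
  marker_masks <- list(Emcn = vessel_mask)
  if (length(spec$arteries)) marker_masks$aSMA <- artery_mask
  if (length(spec$islets)) marker_masks$insulin <- insulin_mask
  pop_markers <- unique(unlist(lapply(spec$cell_populations, `[[`, "markers")))
  for (mk in pop_markers) {
    rows <- cells$type %in% vapply(spec$cell_populations, function(p)
      if (mk %in% p$markers) p$name else "", character(1))
    if (!any(rows)) next
    balls <- cbind(cells$z_um[rows], cells$y_um[rows], cells$x_um[rows],
                   spec$cell_radius_um)
    marker_masks[[mk]] <- array(cpp_rasterize_balls(dm, sp, balls, logical(0)), dim = dm)
  }
  if (any(cells$proliferating)) {
    rows <- cells$proliferating
    balls <- cbind(cells$z_um[rows], cells$y_um[rows], cells$x_um[rows],
                   spec$nucleus_sigma_um)
    marker_masks$Ki67 <- array(cpp_rasterize_balls(dm, sp, balls, logical(0)), dim = dm)
  }

  channel_names <- c(names(marker_masks), "nuclei")
  data <- array(0, dim = c(length(channel_names), dm))
  psf_vox <- spec$psf_sigma_um / sp
  for (ci in seq_along(marker_masks)) {
    ch <- spec$bg + (spec$fg - spec$bg) * marker_masks[[ci]]
    if (spec$psf_sigma_um > 0)
      ch <- array(cpp_gaussian_blur(as.numeric(ch), dm, psf_vox), dim = dm)
    data[ci, , , ] <- ch
  }
  # nuclei: Gaussian blobs at every cell centroid
  nuc <- array(0, dim = dm)
  if (nrow(cells)) {
    iz <- round(cells$z_um / sp[1]) + 1
    iy <- round(cells$y_um / sp[2]) + 1
    ix <- round(cells$x_um / sp[3]) + 1
    nuc[cbind(iz, iy, ix)] <- 1
    nuc <- array(cpp_gaussian_blur(as.numeric(nuc), dm, spec$nucleus_sigma_um / sp), dim = dm)
    if (max(nuc) > 0) nuc <- nuc / max(nuc)
  }
  nuc_ch <- spec$bg + (spec$fg - spec$bg) * nuc
  if (spec$psf_sigma_um > 0)
    nuc_ch <- array(cpp_gaussian_blur(as.numeric(nuc_ch), dm, psf_vox), dim = dm)
  data[length(channel_names), , , ] <- nuc_ch

  if (spec$noise_sd > 0)
    data <- data + rnorm(length(data), 0, spec$noise_sd)
  data[data < 0] <- 0
  grid <- voxel_grid(data, sp, channel_names)

  # --- ground truth --------------------------------------------------------
  seg_m <- seg_matrix(segs)
  analytic_vol <- if (nrow(seg_m))
    sum(pi * seg_m[, 7]^2 * sqrt(rowSums((seg_m[, 4:6, drop = FALSE] -
                                          seg_m[, 1:3, drop = FALSE])^2)))
  else 0
  metrics <- list(
    vessel_volume_fraction = mean(vessel_mask),
    analytic_vessel_volume_fraction = analytic_vol / prod(extent),
    artery_count = length(spec$arteries),
    capillary_diameters_um = if (nrow(seg_m)) 2 * seg_m[, 7] else numeric(),
    artery_diameters_um = vapply(spec$arteries, function(s) 2 * s$radius_um, numeric(1)),
    n_cells = nrow(cells),
    cell_counts = table(cells$type),
    proliferating_fraction = vapply(split(cells$proliferating, cells$type),
                                    mean, numeric(1)),
    islet_insulin_fraction = vapply(spec$islets, function(i)
      if (is.null(i$insulin_fraction)) 1 else i$insulin_fraction, numeric(1)),
    tissue_volume_mm3 = prod(extent) / 1e9)
  truth <- list(vessel_mask = vessel_mask, artery_mask = artery_mask,
                islet_labels = islet_labels, insulin_mask = insulin_mask,
                cells = cells, metrics = metrics,
                segments = segs, artery_segments = spec$arteries)
  list(grid = grid, truth = truth)
}

#' Place cell centroids at a controlled distance from the vessel surface
#'
#' Centroids are drawn (without replacement, seeded) from voxel centres whose
#' exact Euclidean distance to the vessel mask lies in `[d_min, d_max]`
#' micrometres; the degenerate band `[0, 0]` draws from the vessel surface
#' voxels themselves.
#'
#' @param vessel_mask logical `(z, y, x)` array.
#' @param spacing_um voxel pitch `(dz, dy, dx)` in micrometres.
#' @param n number of centroids.
#' @param d_min,d_max distance band in micrometres, `d_min <= d_max`.
#' @param seed integer seed.
#' @return numeric matrix `n x 3` of centroids (z, y, x in micrometres), with
#'   attribute `distance_um` holding each centroid's true distance.
#' @export
place_cells_at_distance <- function(vessel_mask, spacing_um, n, d_min, d_max, seed = 1L) {
  stopifnot(d_min <= d_max, n >= 1)
  if (!any(vessel_mask)) stop("empty vessel mask")
  dm <- dim(vessel_mask)
  set.seed(as.integer(seed))
  if (d_max == 0) {
    bg_edt <- array(cpp_edt(!as.logical(vessel_mask), dm, spacing_um), dim = dm)
    cand <- which(vessel_mask & bg_edt <= min(spacing_um) + 1e-9)
    dvals <- rep(0, length(cand))
  } else {
    edt <- array(cpp_edt(as.logical(vessel_mask), dm, spacing_um), dim = dm)
    cand <- which(edt >= d_min & edt <= d_max)
    dvals <- edt[cand]
  }
  if (length(cand) < n)
    stop(sprintf("infeasible distance band [%g, %g]: %d candidate voxels for %d cells",
                 d_min, d_max, length(cand), n))
  pick <- sample.int(length(cand), n)
  zyx <- arrayInd(cand[pick], dm)
  out <- cbind(z_um = (zyx[, 1] - 1) * spacing_um[1],
               y_um = (zyx[, 2] - 1) * spacing_um[2],
               x_um = (zyx[, 3] - 1) * spacing_um[3])
  attr(out, "distance_um") <- dvals[pick]
  out
}
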