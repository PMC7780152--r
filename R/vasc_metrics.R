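# Vascular metrics -------------------------------------------------------------

#' Vessel density: vessel volume over tissue volume
#'
#' The fraction of the tissue volume occupied by segmented vessels
#' (dimensionless; vessels outside the tissue mask are ignored).
#'
#' @param vessel_mask logical `(z, y, x)` array.
#' @param tissue_mask logical array on the same grid; `NULL` means the whole
#'   volume.
#' @return scalar in `[0, 1]`.
#' @export
vessel_density <- function(vessel_mask, tissue_mask = NULL) {
  if (is.null(tissue_mask)) tissue_mask <- array(TRUE, dim = dim(vessel_mask))
  stopifnot(identical(dim(vessel_mask), dim(tissue_mask)))
  n_tissue <- sum(tissue_mask)
  if (n_tissue == 0) stop("empty tissue mask")
  sum(vessel_mask & tissue_mask) / n_tissue
}

# skeleton of one component: medial ridge of the interior distance transform.
# The raw ridge EDT is used as the local radius: the ridge voxel sits up to
# half a pitch off the true axis (underestimating) while the centre-to-centre
# distance overshoots the surface by up to half a pitch, and the two biases
# largely cancel.
component_skeleton <- function(mask, spacing_um) {
  dm <- dim(mask)
  edt <- array(cpp_edt(!as.logical(mask), dm, spacing_um), dim = dm)
  ridge <- array(cpp_ridge_mask(as.numeric(edt), as.logical(mask), dm, 1e-9), dim = dm)
  radii <- edt[ridge]
  length_um <- cpp_geodesic_diameter(as.logical(mask), dm, spacing_um)
  list(radii_um = radii, length_um = length_um)
}

crop_component <- function(cs, row, pad = 2L) {
  dm <- dim(cs$labels)
  lo <- pmax(c(row$z_min, row$y_min, row$x_min) - pad, 1L)
  hi <- pmin(c(row$z_max, row$y_max, row$x_max) + pad, dm)
  array(cs$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == row$label,
        dim = hi - lo + 1L)
}

#' Identify arteries among alpha-SMA+ components by tubular shape
#'
#' Since alpha-SMA also labels stromal cells, arteries are distinguished by
#' their structure: a component is kept when its skeleton length (geodesic
#' extent of the component) is at least `min_length_um`, its mean radius
#' (interior distance transform on the medial ridge) at least
#' `min_radius_um`, and its elongation `length / (2 * mean radius)` at least
#' `min_elongation`.
#'
#' @param asma_components a [component_set()] of the alpha-SMA channel.
#' @param min_length_um minimum skeleton length (um).
#' @param min_radius_um minimum mean tube radius (um).
#' @param min_elongation minimum length-to-diameter ratio.
#' @return A [component_set()] containing only the arteries; the per-
#'   component tubularity measurements are attached as attribute
#'   `tubularity`.
#' @export
detect_arteries <- function(asma_components, min_length_um = 50,
                            min_radius_um = 3, min_elongation = 2) {
  stopifnot(inherits(asma_components, "component_set"),
            min_length_um > 0, min_radius_um > 0, min_elongation > 0)
  comp <- asma_components$components
  if (!nrow(comp)) return(asma_components)
  meas <- data.frame(label = comp$label, length_um = NA_real_,
                     mean_radius_um = NA_real_, elongation = NA_real_)
  keep <- logical(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    sub <- crop_component(asma_components, comp[i, ])
    sk <- component_skeleton(sub, asma_components$spacing_um)
    r <- mean(sk$radii_um)
    meas$length_um[i] <- sk$length_um
    meas$mean_radius_um[i] <- r
    meas$elongation[i] <- sk$length_um / (2 * r)
    keep[i] <- sk$length_um >= min_length_um && r >= min_radius_um &&
      meas$elongation[i] >= min_elongation
  }
  mask <- array(asma_components$labels %in% comp$label[keep],
                dim = dim(asma_components$labels))
  out <- component_set(mask, asma_components$spacing_um)
  attr(out, "tubularity") <- meas
  out
}

#' Arteries per cubic millimetre of tissue
#'
#' @param artery_count integer count of detected arteries.
#' @param tissue_mask logical `(z, y, x)` array.
#' @param spacing_um voxel pitch in micrometres.
#' @return count per mm^3 (1 mm^3 = 1e9 um^3).
#' @export
artery_density <- function(artery_count, tissue_mask, spacing_um) {
  vol_mm3 <- sum(tissue_mask) * voxel_volume_um3(spacing_um) / 1e9
  if (vol_mm3 <= 0) stop("empty tissue mask")
  artery_count / vol_mm3
}

#' Mean vessel diameter from randomly sampled regions
#'
#' Mirrors caliper measurements on random fields of view with a
#' deterministic estimator: the mask is skeletonised (medial ridge of the
#' interior distance transform) once; then `n_regions` random cubic
#' sub-blocks of side `region_size_um` containing skeleton voxels are drawn
#' (seeded, vessel-free blocks rejected and resampled), and each region's
#' diameter is twice the mean local radius over its skeleton voxels.
#'
#' @param vessel_mask logical `(z, y, x)` array, non-empty.
#' @param spacing_um voxel pitch in micrometres.
#' @param n_regions number of regions (default 7).
#' @param region_size_um cubic sub-block side (um).
#' @param seed integer seed for the region draw.
#' @param max_retries resampling budget per region.
#' @return list with `mean_diameter_um` and `per_region_um`.
#' @export
estimate_diameters <- function(vessel_mask, spacing_um, n_regions = 7,
                               region_size_um = 50, seed = 1L,
                               max_retries = 1000L) {
  stopifnot(n_regions >= 1)
  if (!any(vessel_mask)) stop("empty vessel mask")
  dm <- dim(vessel_mask)
  edt <- array(cpp_edt(!as.logical(vessel_mask), dm, spacing_um), dim = dm)
  ridge <- array(cpp_ridge_mask(as.numeric(edt), as.logical(vessel_mask), dm, 1e-9),
                 dim = dm)
  radius <- edt
  side_vox <- pmax(1L, pmin(dm, as.integer(round(region_size_um / spacing_um))))
  set.seed(as.integer(seed))
  per_region <- numeric(n_regions)
  for (r in seq_len(n_regions)) {
    val <- NA_real_
    for (try in seq_len(max_retries)) {
      lo <- vapply(1:3, function(a)
        if (dm[a] > side_vox[a]) sample.int(dm[a] - side_vox[a] + 1L, 1L) else 1L,
        integer(1))
      hi <- lo + side_vox - 1L
      sub <- ridge[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      if (any(sub)) {
        val <- mean(2 * radius[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]][sub])
        break
      }
    }
    if (is.na(val)) stop("no vessel voxels found in any sampled region")
    per_region[r] <- val
  }
  list(mean_diameter_um = mean(per_region), per_region_um = per_region)
}

#' Vessel density per region, optionally restricted to a vessel phenotype
#'
#' Computes the vessel volume fraction within each labelled region (e.g.
#' islet vs non-islet, selected on insulin expression), optionally counting
#' only a phenotype sub-mask of the vessels (e.g. Emcn-hi capillaries).
#'
#' @param vessel_mask logical `(z, y, x)` array.
#' @param regions a [region_mask()] on the same grid.
#' @param phenotype_mask optional logical array; vessels are intersected
#'   with it first.
#' @return data.frame with `region` and `vessel_density`; empty regions are
#'   omitted with a warning.
#' @export
region_restricted_density <- function(vessel_mask, regions, phenotype_mask = NULL) {
  stopifnot(inherits(regions, "region_mask"),
            identical(dim(vessel_mask), dim(regions$labels)))
  v <- vessel_mask
  if (!is.null(phenotype_mask)) v <- v & phenotype_mask
  ids <- sort(setdiff(unique(as.integer(regions$labels)), 0L))
  out <- data.frame(region = character(), vessel_density = numeric(),
                    stringsAsFactors = FALSE)
  for (id in ids) {
    reg <- regions$labels == id
    n <- sum(reg)
    nm <- regions$label_names[[as.character(id)]]
    if (is.null(nm) || is.na(nm)) nm <- paste0("region", id)
    if (n == 0) { warning("region '", nm, "' has no voxels; omitted"); next }
    out <- rbind(out, data.frame(region = nm, vessel_density = sum(v & reg) / n,
                                 stringsAsFactors = FALSE))
  }
  out
}
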