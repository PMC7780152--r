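# Surface segmentation and cell segmentation -----------------------------------

#' Otsu threshold of an intensity sample
#'
#' Histogram-based between-class-variance maximiser (256 bins over the data
#' range); used as the automatic threshold wherever a manual one is not
#' supplied.
#'
#' @param x numeric vector or array of intensities.
#' @param nbins number of histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Rolling background subtraction
#'
#' Subtracts a Gaussian-smoothed copy of the channel at a scale larger than
#' the objects of interest, clipping at zero: flat fields and slow intensity
#' ramps are suppressed while fine structure (vessels, cells) is preserved.
#'
#' @param channel 3D numeric array `(z, y, x)`.
#' @param spacing_um voxel pitch in micrometres.
#' @param scale_um smoothing scale in micrometres, > 0 and larger than the
#'   object scale.
#' @return array of the same shape, non-negative.
#' @export
subtract_background <- function(channel, spacing_um, scale_um) {
  if (!is.numeric(scale_um) || scale_um <= 0) stop("`scale_um` must be > 0")
  dm <- dim(channel)
  # sigma = scale/3 so ~99% of the kernel mass lies within +/- scale_um
  bg <- array(cpp_gaussian_blur(as.numeric(channel), dm,
                                scale_um / 3 / spacing_um), dim = dm)
  out <- channel - bg
  out[out < 0] <- 0
  out
}

# per-component shape statistics; surface area from a marching-tetrahedra
# mesh of the lightly smoothed component indicator (iso 0.5)
component_stats <- function(labels, spacing_um) {
  dm <- dim(labels)
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  vx <- voxel_volume_um3(spacing_um)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- which(labels == ids[i])
    zyx <- arrayInd(sel, dm)
    nvox <- length(sel)
    bb <- rbind(apply(zyx, 2, min), apply(zyx, 2, max))
    # crop with padding for the mesh
    pad <- 3L
    lo <- pmax(bb[1, ] - pad, 1L); hi <- pmin(bb[2, ] + pad, dm)
    sub <- array(0, dim = hi - lo + 1L)
    sub[cbind(zyx[, 1] - lo[1] + 1L, zyx[, 2] - lo[2] + 1L, zyx[, 3] - lo[3] + 1L)] <- 1
    smoothed <- array(cpp_gaussian_blur(as.numeric(sub), dim(sub), c(1, 1, 1)), dim = dim(sub))
    area <- cpp_isosurface_area(as.numeric(smoothed), dim(sub), spacing_um, 0.5)
    vol <- nvox * vx
    psi <- if (area > 0) pi^(1 / 3) * (6 * vol)^(2 / 3) / area else NA_real_
    # elongation from the coordinate covariance (principal-axis ratio)
    pc <- cbind((zyx[, 1] - 1) * spacing_um[1], (zyx[, 2] - 1) * spacing_um[2],
                (zyx[, 3] - 1) * spacing_um[3])
    elong <- if (nvox >= 4) {
      ev <- sort(eigen(stats::cov(pc), symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      if (ev[2] > 1e-12) sqrt(ev[1] / ev[2]) else Inf
    } else 1
    out[[i]] <- data.frame(
      label = i, voxel_count = nvox, volume_um3 = vol, surface_area_um2 = area,
      sphericity = psi, elongation = elong,
      z_um = mean(pc[, 1]), y_um = mean(pc[, 2]), x_um = mean(pc[, 3]),
      z_min = bb[1, 1], z_max = bb[2, 1], y_min = bb[1, 2], y_max = bb[2, 2],
      x_min = bb[1, 3], x_max = bb[2, 3])
  }
  if (!length(out))
    return(data.frame(label = integer(), voxel_count = integer(),
                      volume_um3 = numeric(), surface_area_um2 = numeric(),
                      sphericity = numeric(), elongation = numeric(),
                      z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      z_min = integer(), z_max = integer(), y_min = integer(),
                      y_max = integer(), x_min = integer(), x_max = integer()))
  do.call(rbind, out)
}

#' Connected components of a binary mask with shape statistics
#'
#' Labels foreground with the chosen connectivity (default 26) and computes,
#' per component: voxel count, physical volume, mesh surface area, sphericity
#' `psi = pi^(1/3) (6V)^(2/3) / A` (1 for a ball), principal-axis elongation,
#' centroid and bounding box.
#'
#' @param mask logical `(z, y, x)` array.
#' @param spacing_um voxel pitch in micrometres.
#' @param connectivity 26 (default) or 6.
#' @return A `component_set`: list with `mask`, `labels`, `components`
#'   (data.frame), `spacing_um`.
#' @export
component_set <- function(mask, spacing_um, connectivity = 26L) {
  dm <- dim(mask)
  labels <- array(cpp_label_components(as.logical(mask), dm, as.integer(connectivity)),
                  dim = dm)
  # relabel contiguously (cpp already emits 1..n in scan order)
  structure(list(mask = array(as.logical(mask), dm), labels = labels,
                 components = component_stats(labels, spacing_um),
                 spacing_um = as.numeric(spacing_um)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("component_set: %d component(s), %d foreground voxels\n",
              nrow(x$components), sum(x$mask)))
  if (nrow(x$components)) print(head(x$components[, c("label", "volume_um3",
                                                      "sphericity", "elongation")], 10))
  invisible(x)
}

#' Segment a marker surface by smoothing and thresholding
#'
#' Gaussian-smooths the channel (sigma in micrometres, anisotropy-aware),
#' thresholds it (a manual value, or `"auto"` for Otsu on the smoothed
#' intensities) and labels 26-connected components with shape statistics.
#' The realized threshold is recorded as attribute `threshold` for the run
#' report: group contrasts should be computed with the same manual threshold
#' on all samples.
#'
#' @param channel 3D numeric array `(z, y, x)`.
#' @param spacing_um voxel pitch in micrometres.
#' @param smooth_sigma_um Gaussian sigma in micrometres (0 = no smoothing).
#' @param threshold numeric, or `"auto"`.
#' @param connectivity 26 (default) or 6.
#' @return A [component_set()]; empty foreground yields a valid empty set.
#' @export
segment_surface <- function(channel, spacing_um, smooth_sigma_um = 1,
                            threshold = "auto", connectivity = 26L) {
  if (anyNA(channel)) stop("channel contains NA/NaN")
  dm <- dim(channel)
  sm <- if (smooth_sigma_um > 0)
    array(cpp_gaussian_blur(as.numeric(channel), dm, smooth_sigma_um / spacing_um), dim = dm)
  else channel
  thr <- if (identical(threshold, "auto")) otsu_threshold(sm) else as.numeric(threshold)
  cs <- component_set(sm > thr, spacing_um, connectivity)
  attr(cs, "threshold") <- thr
  cs
}

#' Remove small high-sphericity components regarded as noise
#'
#' Drops exactly the components with `volume < max_volume_um3` AND
#' `sphericity >= min_sphericity` (small near-spherical specks); everything
#' else, including large blobs and elongated tubes, is retained. Remaining
#' components are relabelled contiguously.
#'
#' @param cs a [component_set()].
#' @param max_volume_um3 size guard in cubic micrometres (> 0).
#' @param min_sphericity sphericity cut in (0, 1].
#' @return filtered [component_set()].
#' @export
filter_noise_components <- function(cs, max_volume_um3 = 500, min_sphericity = 0.8) {
  stopifnot(inherits(cs, "component_set"), max_volume_um3 > 0,
            min_sphericity > 0, min_sphericity <= 1)
  comp <- cs$components
  if (!nrow(comp)) return(cs)
  drop <- comp$volume_um3 < max_volume_um3 & comp$sphericity >= min_sphericity
  keep_ids <- comp$label[!drop]
  mask <- array(cs$labels %in% keep_ids, dim = dim(cs$labels))
  component_set(mask, cs$spacing_um)
}

#' Nuclei-seeded cell segmentation with marker intensities
#'
#' Nuclei are detected as local maxima of the Gaussian-smoothed nuclei
#' channel above a threshold (Otsu by default), with greedy suppression of
#' maxima closer than `min_separation_um`. Each nucleus seeds a watershed on
#' the membrane channel when one is given, otherwise a geodesic nearest-seed
#' partition; growth is bounded by `max_radius_um` from the seed. Per-cell
#' mean marker intensities are computed over the cell territory.
#'
#' @param nuclei_channel 3D numeric array `(z, y, x)`.
#' @param spacing_um voxel pitch in micrometres.
#' @param membrane_channel optional 3D array used as the watershed landscape.
#' @param marker_channels named list of 3D arrays; each yields a
#'   `mean_<name>` column.
#' @param nucleus_sigma_um smoothing sigma for nucleus detection (um).
#' @param threshold numeric or `"auto"` (Otsu on the smoothed channel).
#' @param max_radius_um maximum cell radius (um).
#' @param min_separation_um minimum distance between nuclei (um).
#' @return data.frame, one row per cell: `id`, centroid (`z_um`, `y_um`,
#'   `x_um`), `nucleus_volume_um3`, `territory_volume_um3`, `mean_<marker>`
#'   columns, `phenotype` (filled by [classify_phenotypes()]), `region`,
#'   `distance_to_vessel_um` (filled by [annotate_cell_distances()]). The
#'   cell label volume is attached as attribute `labels`.
#' @export
segment_cells <- function(nuclei_channel, spacing_um, membrane_channel = NULL,
                          marker_channels = list(), nucleus_sigma_um = 2,
                          threshold = "auto", max_radius_um = 8,
                          min_separation_um = 4) {
  dm <- dim(nuclei_channel)
  sm <- array(cpp_gaussian_blur(as.numeric(nuclei_channel), dm,
                                nucleus_sigma_um / spacing_um), dim = dm)
  thr <- if (identical(threshold, "auto")) otsu_threshold(sm) else as.numeric(threshold)
  peaks <- cpp_local_maxima(as.numeric(sm), dm, thr)
  empty_cells <- function() {
    df <- data.frame(id = integer(), z_um = numeric(), y_um = numeric(),
                     x_um = numeric(), nucleus_volume_um3 = numeric(),
                     territory_volume_um3 = numeric(), stringsAsFactors = FALSE)
    for (mk in names(marker_channels)) df[[paste0("mean_", mk)]] <- numeric()
    df$phenotype <- character(); df$region <- character()
    df$distance_to_vessel_um <- numeric()
    df
  }
  if (!length(peaks)) {
    warning("no nuclei detected")
    return(empty_cells())
  }
  # greedy minimum-separation suppression, brightest first
  zyx <- arrayInd(peaks, dm)
  pos <- cbind((zyx[, 1] - 1) * spacing_um[1], (zyx[, 2] - 1) * spacing_um[2],
               (zyx[, 3] - 1) * spacing_um[3])
  ord <- order(sm[peaks], decreasing = TRUE)
  keep <- integer()
  for (i in ord) {
    if (!length(keep)) { keep <- i; next }
    d2 <- (pos[keep, 1] - pos[i, 1])^2 + (pos[keep, 2] - pos[i, 2])^2 +
      (pos[keep, 3] - pos[i, 3])^2
    if (min(d2) >= min_separation_um^2) keep <- c(keep, i)
  }
  keep <- sort(keep)
  seeds <- peaks[keep]
  landscape <- if (is.null(membrane_channel)) numeric(length(sm))
  else as.numeric(array(cpp_gaussian_blur(as.numeric(membrane_channel), dm,
                                          1 / spacing_um), dim = dm))
  labels <- array(cpp_seeded_grow(landscape, seeds, logical(0), dm, spacing_um,
                                  max_radius_um, !is.null(membrane_channel)), dim = dm)
  vx <- voxel_volume_um3(spacing_um)
  n <- length(seeds)
  tab <- tabulate(labels, n)
  nuc_tab <- tabulate(labels[sm >= thr], n)
  szyx <- arrayInd(seeds, dm)
  df <- data.frame(id = seq_len(n),
                   z_um = (szyx[, 1] - 1) * spacing_um[1],
                   y_um = (szyx[, 2] - 1) * spacing_um[2],
                   x_um = (szyx[, 3] - 1) * spacing_um[3],
                   nucleus_volume_um3 = nuc_tab * vx,
                   territory_volume_um3 = tab * vx,
                   stringsAsFactors = FALSE)
  for (mk in names(marker_channels)) {
    ch <- marker_channels[[mk]]
    sums <- as.numeric(rowsum(as.numeric(ch)[labels > 0], labels[labels > 0],
                              reorder = TRUE))
    present <- sort(unique(labels[labels > 0]))
    mean_int <- rep(NA_real_, n)
    mean_int[present] <- sums / tab[present]
    df[[paste0("mean_", mk)]] <- mean_int
  }
  df$phenotype <- "unclassified"
  df$region <- NA_character_
  df$distance_to_vessel_um <- NA_real_
  attr(df, "labels") <- labels
  attr(df, "threshold") <- thr
  df
}

#' Marker-band phenotype rule
#'
#' A cell satisfies a rule when every listed marker's mean intensity falls in
#' the stated band: `neg` is `< t_pos`, `pos` is `>= t_pos`, `lo` is
#' `[t_pos, t_hi)` and `hi` is `>= t_hi` (boundaries inclusive on the
#' positive side).
#'
#' @param label phenotype label assigned on match, e.g. `"CD31+Emcn-hi"`.
#' @param ... named bands, one per marker, each one of
#'   `"neg"`, `"pos"`, `"lo"`, `"hi"` — e.g. `CD31 = "pos", Emcn = "hi"`.
#' @return A `phenotype_rule`.
#' @export
phenotype_rule <- function(label, ...) {
  bands <- c(...)
  stopifnot(length(bands) >= 1, all(bands %in% c("neg", "pos", "lo", "hi")),
            !is.null(names(bands)), all(nzchar(names(bands))))
  structure(list(label = label, bands = bands), class = "phenotype_rule")
}

# default per-marker thresholds: t_pos by Otsu over the cells' intensities,
# t_hi the median of the above-t_pos intensities
default_marker_thresholds <- function(cells, markers) {
  out <- list()
  for (mk in markers) {
    v <- cells[[paste0("mean_", mk)]]
    v <- v[is.finite(v)]
    t_pos <- otsu_threshold(v)
    above <- v[v >= t_pos]
    t_hi <- if (length(above)) median(above) else t_pos
    out[[mk]] <- c(t_pos = t_pos, t_hi = max(t_hi, t_pos + 1e-12))
  }
  out
}

#' Assign phenotype labels to segmented cells
#'
#' Rules are evaluated in the given priority order; each cell receives the
#' first matching rule's label, else `"unclassified"`.
#'
#' @param cells cell table from [segment_cells()].
#' @param rules list of [phenotype_rule()].
#' @param thresholds optional named list, per marker `c(t_pos =, t_hi =)`;
#'   missing markers get data-driven defaults (Otsu `t_pos`, median-of-
#'   positives `t_hi`).
#' @return the cell table with `phenotype` filled; the realized thresholds
#'   are attached as attribute `marker_thresholds`.
#' @export
classify_phenotypes <- function(cells, rules, thresholds = NULL) {
  markers <- unique(unlist(lapply(rules, function(r) names(r$bands))))
  missing_mk <- markers[!paste0("mean_", markers) %in% names(cells)]
  if (length(missing_mk))
    stop("unknown marker(s) in rules: ", paste(missing_mk, collapse = ", "))
  thr <- default_marker_thresholds(cells, markers)
  for (mk in names(thresholds)) thr[[mk]] <- thresholds[[mk]]
  if (!nrow(cells)) return(cells)
  lab <- rep("unclassified", nrow(cells))
  for (rule in rev(rules)) { # reverse so earlier rules overwrite: priority order
    ok <- rep(TRUE, nrow(cells))
    for (mk in names(rule$bands)) {
      v <- cells[[paste0("mean_", mk)]]
      t_pos <- thr[[mk]]["t_pos"]; t_hi <- thr[[mk]]["t_hi"]
      ok <- ok & switch(rule$bands[[mk]],
                        neg = v < t_pos,
                        pos = v >= t_pos,
                        lo = v >= t_pos & v < t_hi,
                        hi = v >= t_hi)
    }
    ok[is.na(ok)] <- FALSE
    lab[ok] <- rule$label
  }
  cells$phenotype <- lab
  attr(cells, "marker_thresholds") <- thr
  cells
}
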