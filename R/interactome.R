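# Cell-vessel interactome ------------------------------------------------------
#
# Distance-transform based proximity analysis: per-voxel Euclidean distance
# to the nearest vessel voxel (anisotropic, in micrometres), per-cell
# distances by trilinear interpolation at the centroid, and the proximity
# rule that a cell belongs to a vessel subset's interactome when its
# distance is <= 18 um (inclusive).

#' Anisotropic Euclidean distance field to the vessel mask
#'
#' Exact Euclidean distance transform of the complement of the vessel mask:
#' 0 on vessel voxels, the distance in micrometres to the nearest vessel
#' voxel elsewhere. Anisotropic spacing is honoured exactly.
#'
#' @param vessel_mask logical `(z, y, x)` array.
#' @param spacing_um voxel pitch `(dz, dy, dx)` in micrometres.
#' @return A `distance_field`: numeric array with attribute `spacing_um`.
#'   An empty mask yields a field of `Inf` with a warning.
#' @export
distance_to_vessels <- function(vessel_mask, spacing_um) {
  dm <- dim(vessel_mask)
  if (!any(vessel_mask)) {
    warning("empty vessel mask: distance field is infinite")
    field <- array(Inf, dim = dm)
  } else {
    field <- array(cpp_edt(as.logical(vessel_mask), dm, spacing_um), dim = dm)
  }
  attr(field, "spacing_um") <- as.numeric(spacing_um)
  class(field) <- c("distance_field", class(field))
  field
}

# trilinear interpolation of a (z, y, x) field at physical positions (um)
interp_trilinear <- function(field, spacing_um, z_um, y_um, x_um) {
  dm <- dim(field)
  gz <- z_um / spacing_um[1]; gy <- y_um / spacing_um[2]; gx <- x_um / spacing_um[3]
  if (any(gz < -1e-9 | gz > dm[1] - 1 + 1e-9 |
          gy < -1e-9 | gy > dm[2] - 1 + 1e-9 |
          gx < -1e-9 | gx > dm[3] - 1 + 1e-9))
    stop("centroid outside grid bounds")
  z0 <- pmin(pmax(floor(gz), 0), dm[1] - 2); fz <- pmin(pmax(gz - z0, 0), 1)
  y0 <- pmin(pmax(floor(gy), 0), dm[2] - 2); fy <- pmin(pmax(gy - y0, 0), 1)
  x0 <- pmin(pmax(floor(gx), 0), dm[3] - 2); fx <- pmin(pmax(gx - x0, 0), 1)
  if (dm[1] == 1) { z0 <- 0; fz <- 0 }
  if (dm[2] == 1) { y0 <- 0; fy <- 0 }
  if (dm[3] == 1) { x0 <- 0; fx <- 0 }
  g <- function(dz, dy, dx)
    field[cbind(z0 + dz + 1, y0 + dy + 1, x0 + dx + 1)]
  w <- function(dz, dy, dx)
    (dz * fz + (1 - dz) * (1 - fz)) * (dy * fy + (1 - dy) * (1 - fy)) *
    (dx * fx + (1 - dx) * (1 - fx))
  out <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    out <- out + w(dz, dy, dx) * g(min(dz, dm[1] - 1), min(dy, dm[2] - 1),
                                   min(dx, dm[3] - 1))
  out
}

#' Annotate cells with their distance to the vessel surface
#'
#' Fills `distance_to_vessel_um` by trilinear interpolation of the distance
#' field at each cell centroid.
#'
#' @param cells cell table with centroid columns `z_um`, `y_um`, `x_um`.
#' @param field a [distance_to_vessels()] field.
#' @return the cell table with `distance_to_vessel_um` filled (micrometres).
#' @export
annotate_cell_distances <- function(cells, field) {
  stopifnot(inherits(field, "distance_field"))
  if (!nrow(cells)) { cells$distance_to_vessel_um <- numeric(0); return(cells) }
  sp <- attr(field, "spacing_um")
  cells$distance_to_vessel_um <- interp_trilinear(unclass(field), sp,
                                                  cells$z_um, cells$y_um, cells$x_um)
  cells
}

#' Interactome membership under the proximity rule
#'
#' A cell is within the interactome of the blood vessels when its distance
#' is at most `max_distance_um` (18 um by default, boundary inclusive).
#'
#' @param cells cell table with `distance_to_vessel_um` filled.
#' @param max_distance_um proximity threshold in micrometres.
#' @return the cell table with a logical `member` column.
#' @export
interactome_membership <- function(cells, max_distance_um = 18) {
  if (is.null(cells$distance_to_vessel_um) ||
      (nrow(cells) && anyNA(cells$distance_to_vessel_um)))
    stop("cell distances not annotated; run annotate_cell_distances() first")
  cells$member <- cells$distance_to_vessel_um <= max_distance_um
  cells
}

#' Vessel-subset by cell-type interaction matrix
#'
#' For each vessel subset (its own mask, hence its own distance field) and
#' each cell type, counts the cells of that type within the proximity
#' threshold. An interaction is marked `present` when the within-threshold
#' fraction reaches `presence_min_fraction`.
#'
#' @param cells typed cell table (a `type` or `phenotype` column).
#' @param vessel_subsets named list of logical `(z, y, x)` masks.
#' @param spacing_um voxel pitch in micrometres.
#' @param max_distance_um proximity threshold (um, inclusive).
#' @param presence_min_fraction minimum fraction declaring an interaction
#'   present.
#' @param cell_types optional fixed cell-type vocabulary (column set); by
#'   default the types observed in `cells`. Fix this when comparing
#'   conditions so both matrices share the same columns.
#' @param condition optional condition label (e.g. `"young"`, `"aged"`).
#' @return An `interaction_matrix`: long-format data.frame with columns
#'   `subset`, `cell_type`, `n_within`, `n_total`, `fraction`, `present`;
#'   threshold and condition kept as attributes. Empty subsets are omitted
#'   with a warning; a type with no cells gets `fraction = 0` and is flagged
#'   in `undefined`.
#' @export
build_interactome <- function(cells, vessel_subsets, spacing_um,
                              max_distance_um = 18,
                              presence_min_fraction = 0.1,
                              cell_types = NULL,
                              condition = NA_character_) {
  type_col <- if (!is.null(cells$type)) "type" else "phenotype"
  types <- if (is.null(cell_types)) sort(unique(as.character(cells[[type_col]])))
  else as.character(cell_types)
  out <- list()
  for (sub_name in names(vessel_subsets)) {
    m <- vessel_subsets[[sub_name]]
    if (!any(m)) { warning("vessel subset '", sub_name, "' is empty; omitted"); next }
    field <- suppressWarnings(distance_to_vessels(m, spacing_um))
    d <- if (nrow(cells)) interp_trilinear(unclass(field), spacing_um,
                                           cells$z_um, cells$y_um, cells$x_um)
    else numeric(0)
    for (ty in types) {
      sel <- cells[[type_col]] == ty
      n_total <- sum(sel)
      n_within <- sum(d[sel] <= max_distance_um)
      frac <- if (n_total > 0) n_within / n_total else 0
      out[[length(out) + 1L]] <- data.frame(
        subset = sub_name, cell_type = ty, n_within = n_within,
        n_total = n_total, fraction = frac,
        present = frac >= presence_min_fraction,
        undefined = n_total == 0, stringsAsFactors = FALSE)
    }
  }
  mat <- if (length(out)) do.call(rbind, out) else
    data.frame(subset = character(), cell_type = character(),
               n_within = integer(), n_total = integer(), fraction = numeric(),
               present = logical(), undefined = logical(),
               stringsAsFactors = FALSE)
  attr(mat, "max_distance_um") <- max_distance_um
  attr(mat, "presence_min_fraction") <- presence_min_fraction
  attr(mat, "condition") <- condition
  class(mat) <- c("interaction_matrix", "data.frame")
  mat
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix (threshold %g um, condition: %s)\n",
              attr(x, "max_distance_um"), attr(x, "condition")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Differential interactome between two conditions
#'
#' Compares presence calls between two interaction matrices sharing the same
#' subsets, cell types and threshold: an interaction is `gained` when
#' present only in the second (aged) condition, `lost` when present only in
#' the first (young), `stable` otherwise.
#'
#' @param m_young,m_aged [build_interactome()] results on the same
#'   vocabulary.
#' @return data.frame with `subset`, `cell_type`, `status`.
#' @export
differential_interactome <- function(m_young, m_aged) {
  key <- function(m) paste(m$subset, m$cell_type, sep = "\r")
  if (!setequal(key(m_young), key(m_aged)) ||
      nrow(m_young) != nrow(m_aged))
    stop("interaction matrices have different subset/cell-type vocabularies")
  if (!isTRUE(all.equal(attr(m_young, "max_distance_um"),
                        attr(m_aged, "max_distance_um"))))
    stop("interaction matrices use different distance thresholds")
  idx <- match(key(m_young), key(m_aged))
  status <- ifelse(!m_young$present & m_aged$present[idx], "gained",
                   ifelse(m_young$present & !m_aged$present[idx], "lost", "stable"))
  data.frame(subset = m_young$subset, cell_type = m_young$cell_type,
             status = status, stringsAsFactors = FALSE)
}
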