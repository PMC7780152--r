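# End-to-end pipeline ----------------------------------------------------------

#' Run the full quantification pipeline on a multi-channel volume
#'
#' Segments vessels from the endothelial channel (background subtraction,
#' smoothing, thresholding, sphericity noise filter), detects arteries on
#' the alpha-SMA channel by tubular shape, computes vessel density, artery
#' density and mean vessel diameter, segments cells from the nuclei channel,
#' classifies phenotypes, annotates cell-vessel distances and the
#' interactome membership, and assembles a long-format quantification table.
#'
#' @param grid a [voxel_grid()].
#' @param vessel_marker channel name of the endothelial marker.
#' @param artery_marker channel name of the mural/artery marker (`NULL` to
#'   skip artery analysis).
#' @param nuclei_channel channel name of the nuclear stain.
#' @param marker_channels channel names used for per-cell intensities;
#'   default: every channel except the vessel, artery and nuclei ones.
#' @param tissue_mask logical array (default: the whole volume).
#' @param regions optional [region_mask()] for region-restricted densities.
#' @param rules list of [phenotype_rule()] for cell typing.
#' @param vessel_threshold,artery_threshold manual thresholds or `"auto"`.
#' @param smooth_sigma_um smoothing sigma for surface segmentation (um).
#' @param background_scale_um background-subtraction scale (um); 0 skips.
#' @param noise_max_volume_um3,noise_min_sphericity sphericity noise filter.
#' @param max_distance_um interactome proximity threshold (um).
#' @param max_cell_radius_um bound for the seeded cell segmentation (um).
#' @param diameter_seed seed for the random diameter regions.
#' @param sample_id,group identifiers carried into the quantification table.
#' @return list with `vessels` (filtered [component_set()]), `arteries`,
#'   `cells` (annotated cell table), `metrics` (named list of scalars),
#'   `region_density` (data.frame or NULL), `quant` (a [quant_table()]) and
#'   `thresholds` (realized thresholds for the run report).
#' @export
run_pipeline <- function(grid,
                         vessel_marker = "Emcn",
                         artery_marker = NULL,
                         nuclei_channel = "nuclei",
                         marker_channels = NULL,
                         tissue_mask = NULL,
                         regions = NULL,
                         rules = list(),
                         vessel_threshold = "auto",
                         artery_threshold = "auto",
                         smooth_sigma_um = 0.5,
                         background_scale_um = 0,
                         noise_max_volume_um3 = 500,
                         noise_min_sphericity = 0.8,
                         max_distance_um = 18,
                         max_cell_radius_um = 8,
                         diameter_seed = 1L,
                         sample_id = "sample1", group = "group1") {
  stopifnot(inherits(grid, "voxel_grid"))
  sp <- grid$spacing_um
  dm <- grid_dim(grid)
  if (is.null(tissue_mask)) tissue_mask <- array(TRUE, dim = dm)

  ch_vessel <- get_channel(grid, vessel_marker)
  if (background_scale_um > 0)
    ch_vessel <- subtract_background(ch_vessel, sp, background_scale_um)
  vessels <- segment_surface(ch_vessel, sp, smooth_sigma_um, vessel_threshold)
  thresholds <- list(vessel = attr(vessels, "threshold"))
  vessels <- filter_noise_components(vessels, noise_max_volume_um3,
                                     noise_min_sphericity)
  vd <- vessel_density(vessels$mask, tissue_mask)
  diam <- if (any(vessels$mask))
    estimate_diameters(vessels$mask, sp, seed = diameter_seed)
  else list(mean_diameter_um = NA_real_, per_region_um = numeric())

  arteries <- NULL
  artery_count <- NA_integer_
  artery_dens <- NA_real_
  artery_diam <- NA_real_
  if (!is.null(artery_marker)) {
    ch_asma <- get_channel(grid, artery_marker)
    if (background_scale_um > 0)
      ch_asma <- subtract_background(ch_asma, sp, background_scale_um)
    asma <- segment_surface(ch_asma, sp, smooth_sigma_um, artery_threshold)
    thresholds$artery <- attr(asma, "threshold")
    arteries <- detect_arteries(asma)
    artery_count <- nrow(arteries$components)
    artery_dens <- artery_density(artery_count, tissue_mask, sp)
    artery_diam <- if (artery_count > 0)
      estimate_diameters(arteries$mask, sp, seed = diameter_seed)$mean_diameter_um
    else NA_real_
  }

  all_markers <- setdiff(grid$channel_names,
                         c(nuclei_channel, na.omit(c(vessel_marker, artery_marker))))
  if (is.null(marker_channels)) marker_channels <- all_markers
  mk_list <- lapply(marker_channels, function(m) get_channel(grid, m))
  names(mk_list) <- marker_channels
  cells <- segment_cells(get_channel(grid, nuclei_channel), sp,
                         marker_channels = mk_list,
                         max_radius_um = max_cell_radius_um)
  thresholds$nuclei <- attr(cells, "threshold")
  if (length(rules) && nrow(cells)) cells <- classify_phenotypes(cells, rules)
  if (any(vessels$mask)) {
    field <- distance_to_vessels(vessels$mask, sp)
    cells <- annotate_cell_distances(cells, field)
    cells <- interactome_membership(cells, max_distance_um)
  }

  region_density <- if (!is.null(regions))
    region_restricted_density(vessels$mask, regions)
  else NULL

  metrics <- list(vessel_density = vd,
                  mean_capillary_diameter_um = diam$mean_diameter_um,
                  artery_count = artery_count,
                  artery_density_per_mm3 = artery_dens,
                  mean_artery_diameter_um = artery_diam,
                  n_cells = nrow(cells))
  qt <- quant_table(
    sample_id = sample_id, group = group, region = "tissue",
    metric_name = "vessel_density", value = vd, units = "")
  add_row <- function(qt, region, name, value, units) {
    if (is.na(value)) return(qt)
    rbind(qt, quant_table(sample_id, group, region, name, value, units))
  }
  qt <- add_row(qt, "tissue", "mean_capillary_diameter", diam$mean_diameter_um, "um")
  qt <- add_row(qt, "tissue", "artery_count", artery_count, "")
  qt <- add_row(qt, "tissue", "artery_density", artery_dens, "per_mm3")
  qt <- add_row(qt, "tissue", "mean_artery_diameter", artery_diam, "um")
  qt <- add_row(qt, "tissue", "n_cells", nrow(cells), "")
  if (!is.null(region_density))
    for (i in seq_len(nrow(region_density)))
      qt <- add_row(qt, region_density$region[i], "vessel_density",
                    region_density$vessel_density[i], "")
  class(qt) <- c("quant_table", "data.frame")

  list(vessels = vessels, arteries = arteries, cells = cells,
       metrics = metrics, region_density = region_density, quant = qt,
       thresholds = thresholds)
}
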