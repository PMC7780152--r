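# Scalar quantifications and group statistics ---------------------------------

#' Stained-area fraction within a region
#'
#' `100 * |marker AND region| / |region|` by voxel measure — e.g. the
#' insulin+ (beta-cell) or VEGFA+ percentage of a pancreatic islet.
#'
#' @param marker_mask logical `(z, y, x)` array of marker-positive voxels.
#' @param region_mask logical array on the same grid, non-empty.
#' @return percentage in `[0, 100]`.
#' @export
area_fraction <- function(marker_mask, region_mask) {
  stopifnot(identical(dim(marker_mask), dim(region_mask)))
  n <- sum(region_mask)
  if (n == 0) stop("empty region mask")
  100 * sum(marker_mask & region_mask) / n
}

# resolve a cell-selection rule: a phenotype/type label or a predicate
resolve_rule <- function(cells, rule) {
  if (is.function(rule)) return(isTRUE_vec(rule(cells)))
  lab <- as.character(rule)
  hit <- rep(FALSE, nrow(cells))
  if (!is.null(cells$phenotype)) hit <- hit | cells$phenotype %in% lab
  if (!is.null(cells$type)) hit <- hit | cells$type %in% lab
  hit
}

isTRUE_vec <- function(x) { x[is.na(x)] <- FALSE; as.logical(x) }

#' Fraction of positive cells within a reference population
#'
#' `100 * n(numerator AND denominator) / n(denominator)` — e.g. Ki67+ beta
#' cells normalised to all beta cells of an islet.
#'
#' @param cells cell table.
#' @param numerator_rule,denominator_rule either a phenotype/type label
#'   (character) or a predicate `function(cells) -> logical`.
#' @return percentage; `NA` with attribute `undefined = TRUE` (and a
#'   warning) when the denominator is empty.
#' @export
positive_fraction <- function(cells, numerator_rule, denominator_rule) {
  den <- resolve_rule(cells, denominator_rule)
  num <- resolve_rule(cells, numerator_rule)
  if (!sum(den)) {
    warning("empty denominator population; fraction undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  100 * sum(num & den) / sum(den)
}

#' Cell count per cubic millimetre of tissue
#'
#' @param cells cell table.
#' @param type cell type/phenotype label (or predicate) to count.
#' @param tissue_mask logical `(z, y, x)` array.
#' @param spacing_um voxel pitch in micrometres.
#' @return count per mm^3.
#' @export
count_per_volume <- function(cells, type, tissue_mask, spacing_um) {
  vol_mm3 <- sum(tissue_mask) * voxel_volume_um3(spacing_um) / 1e9
  if (vol_mm3 <= 0) stop("empty tissue mask")
  sum(resolve_rule(cells, type)) / vol_mm3
}

#' Follicle density over the gland outline
#'
#' Component count divided by the gland measure: per mm^2 for a single-slice
#' gland outline, per mm^3 for a 3D one (auto-detected from the z extent,
#' overridable).
#'
#' @param follicles a [component_set()] of follicle lumina.
#' @param gland_mask logical array outlining the whole gland (e.g. from the
#'   nuclear stain), non-empty.
#' @param spacing_um voxel pitch in micrometres.
#' @param mode `"auto"`, `"2d"` or `"3d"`.
#' @return count per mm^2 (2d) or per mm^3 (3d), with attribute `units`.
#' @export
follicle_density <- function(follicles, gland_mask, spacing_um, mode = "auto") {
  stopifnot(inherits(follicles, "component_set"))
  n_gland <- sum(gland_mask)
  if (n_gland == 0) stop("empty gland mask")
  n <- nrow(follicles$components)
  if (mode == "auto") mode <- if (dim(gland_mask)[1] == 1L) "2d" else "3d"
  if (mode == "2d") {
    area_mm2 <- n_gland * spacing_um[2] * spacing_um[3] / 1e6
    structure(n / area_mm2, units = "per_mm2")
  } else {
    vol_mm3 <- n_gland * voxel_volume_um3(spacing_um) / 1e9
    structure(n / vol_mm3, units = "per_mm3")
  }
}

#' Ordinal expression level from mean intensity
#'
#' Half-open binning of mean intensities into the five ordinal levels used
#' for marker-by-region expression heatmaps: `none` `[0, e1)`, `low`
#' `[e1, e2)`, `medium` `[e2, e3)`, `high` `[e3, e4)`, `very_high`
#' `[e4, Inf)`.
#'
#' @param mean_intensity numeric vector of non-negative intensities.
#' @param edges four strictly ascending thresholds `c(e1, e2, e3, e4)`; by
#'   default the 20/40/60/80% quantiles of the positive intensities.
#' @return ordered factor with levels
#'   `none < low < medium < high < very_high`.
#' @export
bin_expression <- function(mean_intensity, edges = NULL) {
  if (is.null(edges)) {
    pos <- mean_intensity[mean_intensity > 0]
    if (length(pos) < 5) stop("too few positive intensities to derive edges")
    edges <- unname(quantile(pos, c(0.2, 0.4, 0.6, 0.8)))
  }
  if (length(edges) != 4L || any(diff(edges) <= 0))
    stop("`edges` must be four strictly ascending thresholds")
  lv <- c("none", "low", "medium", "high", "very_high")
  idx <- findInterval(mean_intensity, edges) + 1L # half-open: [e_k, e_{k+1})
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Pearson correlation between paired per-islet metrics
#'
#' E.g. endothelial-cell proliferation against beta-cell proliferation
#' across islets.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @return list with `r`, `p` (two-sided) and `n`; zero variance in either
#'   vector yields `r = NA` flagged `undefined` with a warning.
#' @export
correlate_metrics <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x), undefined = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare a metric between groups (t-test or ANOVA + Tukey)
#'
#' Two groups: two-tailed unpaired Student's t-test (equal variance; Welch
#' behind `welch = TRUE`). More than two groups: one-way ANOVA with Tukey's
#' honest significant difference for all pairwise comparisons. Group means
#' and standard deviations are reported alongside.
#'
#' @param values named list of numeric vectors, one per group; at least two
#'   groups with at least two values each.
#' @param metric optional metric name carried through to the output.
#' @param welch use the Welch (unequal-variance) t-test for two groups.
#' @return A `group_comparison`: list with `metric`, `groups`, `means`,
#'   `sds`, `n`, `test`, `statistic`, `p_value`, and for > 2 groups a
#'   `tukey` data.frame of pairwise adjusted p-values.
#' @export
compare_groups <- function(values, metric = NA_character_, welch = FALSE) {
  if (!is.list(values) || length(values) < 2 || is.null(names(values)))
    stop("`values` must be a named list with at least two groups")
  sizes <- vapply(values, length, integer(1))
  if (any(sizes < 2)) stop("every group needs at least two values")
  groups <- names(values)
  means <- vapply(values, mean, numeric(1))
  sds <- vapply(values, sd, numeric(1))
  out <- list(metric = metric, groups = groups, means = means, sds = sds,
              n = sizes)
  if (length(values) == 2) {
    tt <- t.test(values[[1]], values[[2]], var.equal = !welch)
    out$test <- if (welch) "welch_t" else "student_t"
    out$statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
    out$tukey <- NULL
  } else {
    df <- data.frame(value = unlist(values, use.names = FALSE),
                     group = factor(rep(groups, sizes), levels = groups))
    fit <- aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    out$test <- "anova_tukey"
    out$statistic <- an[["F value"]][1]
    out$p_value <- an[["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$group
    out$tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison%s: %s\n",
              if (is.na(x$metric)) "" else paste0(" [", x$metric, "]"), x$test))
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: mean %.4g +/- %.4g sd (n=%d)\n",
                x$groups[i], x$means[i], x$sds[i], x$n[i]))
  cat(sprintf("  statistic = %.6g, p = %.6g\n", x$statistic, x$p_value))
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    for (i in seq_len(nrow(x$tukey)))
      cat(sprintf("    %s: p_adj = %.6g\n", x$tukey$pair[i], x$tukey$p_adj[i]))
  }
  invisible(x)
}
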