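test_that("area fractions follow the stained-area ratio", {
  dm <- c(16L, 24L, 24L)
  region <- array(TRUE, dim = dm)
  expect_equal(area_fraction(region, region), 100)
  expect_equal(area_fraction(array(FALSE, dim = dm), region), 0)
  expect_error(area_fraction(region, array(FALSE, dim = dm)), "empty region")
  # planted islet with a 40% insulin+ core
  sp <- SP_DEFAULT
  spec <- phantom_spec(shape = c(64, 128, 128), spacing_um = sp,
                       vessels = list(list(p1 = c(10, 5, 10), p2 = c(10, 60, 10),
                                           radius_um = 2.5)),
                       islets = list(list(center = c(26, 44, 44), radius_um = 22,
                                          insulin_fraction = 0.4)),
                       seed = 8)
  ph <- generate_phantom(spec)
  ins <- get_channel(ph$grid, "insulin") > 105
  got <- area_fraction(ins, ph$truth$islet_labels > 0)
  expect_equal(got, 40, tolerance = 0.05)
  # padding-invariance: embedding in a larger empty volume changes nothing
  big <- array(FALSE, dim = dm + 8L)
  bigr <- big
  big[1:dm[1], 1:dm[2], 1:dm[3]] <- region
  bigr[1:dm[1], 1:dm[2], 1:dm[3]] <- region
  expect_equal(area_fraction(big, bigr), area_fraction(region, region))
})

test_that("positive fractions normalise within the reference population", {
  cells <- data.frame(id = 1:10,
                      phenotype = c(rep("ki67_beta", 2), rep("beta", 6),
                                    rep("macrophage", 2)))
  both <- function(c) c$phenotype %in% c("beta", "ki67_beta")
  expect_equal(positive_fraction(cells, "ki67_beta", both), 25)
  expect_equal(positive_fraction(cells, both, both), 100)
  expect_warning(out <- positive_fraction(cells, "ki67_beta", "absent"),
                 "undefined")
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})

test_that("planted proliferating fraction is recovered end to end", {
  ph <- demo_phantom(seed = 9, n_macrophage = 60, n_beta = 150, prolif = 0.2)
  cells <- demo_cells(ph)
  cells <- classify_phenotypes(cells, list(
    phenotype_rule("ki67_beta", CXCR4 = "pos", Ki67 = "pos"),
    phenotype_rule("beta", CXCR4 = "pos"),
    phenotype_rule("macrophage", CD68 = "pos")))
  frac <- positive_fraction(cells, "ki67_beta",
                            function(c) c$phenotype %in% c("beta", "ki67_beta"))
  se <- 100 * sqrt(0.2 * 0.8 / 150)
  expect_equal(frac, 20, tolerance = 2 * se / 20)
})

test_that("counts per volume use mm^3 and recover planted densities", {
  cells <- data.frame(id = 1:10, type = "macrophage")
  tissue <- array(TRUE, dim = c(100L, 100L, 100L)) # 0.001 mm^3 at 1 um voxels
  expect_equal(count_per_volume(cells, "macrophage", tissue, c(1, 1, 1)), 10000)
  expect_equal(count_per_volume(cells[0, ], "macrophage", tissue, c(1, 1, 1)), 0)
  expect_error(count_per_volume(cells, "macrophage",
                                array(FALSE, dim = c(2L, 2L, 2L)), c(1, 1, 1)),
               "empty tissue")
})

test_that("follicle density divides count by the gland measure", {
  sp <- c(1, 1, 1)
  dm <- c(24L, 100L, 100L)
  foll <- ball_mask(dm, sp, c(12, 25, 25), 5) | ball_mask(dm, sp, c(12, 75, 75), 5)
  cs <- component_set(foll, sp)
  gland <- array(TRUE, dim = dm)
  d3 <- follicle_density(cs, gland, sp)
  expect_equal(as.numeric(d3), 2 / (prod(dm) / 1e9))
  expect_identical(attr(d3, "units"), "per_mm3")
  # single-slice mode reports per mm^2: 5 follicles in 0.5 mm^2 -> 10
  slice <- array(TRUE, dim = c(1L, 1000L, 500L))
  cs5 <- structure(list(mask = slice, labels = slice,
                        components = data.frame(label = 1:5),
                        spacing_um = sp), class = "component_set")
  d2 <- follicle_density(cs5, slice, sp)
  expect_equal(as.numeric(d2), 10)
  expect_identical(attr(d2, "units"), "per_mm2")
  expect_error(follicle_density(cs, array(FALSE, dim = dm), sp), "empty gland")
})

test_that("ordinal expression binning is half-open and monotone", {
  edges <- c(10, 20, 30, 40)
  expect_identical(as.character(bin_expression(0, edges)), "none")
  expect_identical(as.character(bin_expression(30, edges)), "high") # at e3
  expect_identical(as.character(bin_expression(c(5, 15, 25, 35, 45), edges)),
                   c("none", "low", "medium", "high", "very_high"))
  x <- sort(runif(50, 0, 60))
  lv <- bin_expression(x, edges)
  expect_true(all(diff(as.integer(lv)) >= 0))
  expect_error(bin_expression(1, c(10, 10, 30, 40)), "ascending")
})

test_that("correlation handles perfect, null and degenerate inputs", {
  x <- 1:10
  out <- correlate_metrics(x, 2 * x)
  expect_equal(out$r, 1)
  expect_lt(out$p, 1e-10)
  expect_error(correlate_metrics(1:2, 1:2), "at least 3")
  expect_warning(flat <- correlate_metrics(x, rep(1, 10)), "zero variance")
  expect_true(is.na(flat$r))
  # under independence, |r| is small in most seeded replicates
  set.seed(42)
  rs <- replicate(40, abs(correlate_metrics(rnorm(100), rnorm(100))$r))
  expect_gte(mean(rs < 0.25), 0.95)
})

test_that("two-group comparison matches the closed-form pooled t-test", {
  g <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)
  # hand-computed pooled-variance t for {1..4} vs {11..14}
  a <- c(1, 2, 3, 4); b <- c(11, 12, 13, 14)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_ref <- 2 * pt(-abs(t_ref), 6)
  g2 <- compare_groups(list(a = a, b = b))
  expect_equal(g2$statistic, t_ref, tolerance = 1e-12)
  expect_equal(g2$p_value, p_ref, tolerance = 1e-12)
  expect_identical(g2$test, "student_t")
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "at least two values")
})

test_that("three groups use ANOVA with Tukey HSD and match closed forms", {
  set.seed(1)
  vals <- list(juvenile = rnorm(10, 10), adult = rnorm(10, 10),
               aged = rnorm(10, 13))
  g <- compare_groups(vals)
  expect_identical(g$test, "anova_tukey")
  # independent reference: F from explicit sums of squares
  all_v <- unlist(vals)
  grp <- rep(names(vals), each = 10)
  ssb <- sum(vapply(vals, function(v) 10 * (mean(v) - mean(all_v))^2, numeric(1)))
  ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  f_ref <- (ssb / 2) / (ssw / 27)
  expect_equal(g$statistic, f_ref, tolerance = 1e-10)
  expect_equal(g$p_value, pf(f_ref, 2, 27, lower.tail = FALSE), tolerance = 1e-10)
  # Tukey adjusted p from the studentised range distribution
  mse <- ssw / 27
  q_ref <- abs(mean(vals$aged) - mean(vals$juvenile)) / sqrt(mse / 10)
  p_ref <- ptukey(q_ref, 3, 27, lower.tail = FALSE)
  expect_equal(g$tukey$p_adj[g$tukey$pair == "aged-juvenile"], p_ref,
               tolerance = 1e-10)
  expect_true(all(g$tukey$p_adj >= 0 & g$tukey$p_adj <= 1))
  # with a 3-sd shift only the shifted pairs reach significance
  expect_lt(g$p_value, 0.05)
  expect_lt(g$tukey$p_adj[g$tukey$pair == "aged-adult"], 0.05)
  expect_gt(g$tukey$p_adj[g$tukey$pair == "adult-juvenile"], 0.05)
})

test_that("for two groups the ANOVA F equals t squared", {
  set.seed(2)
  a <- rnorm(8); b <- rnorm(8, 1)
  tt <- compare_groups(list(a = a, b = b))
  df <- data.frame(v = c(a, b), g = factor(rep(c("a", "b"), each = 8)))
  an <- summary(aov(v ~ g, data = df))[[1]]
  expect_equal(an[["F value"]][1], tt$statistic^2, tolerance = 1e-10)
  expect_equal(an[["Pr(>F)"]][1], tt$p_value, tolerance = 1e-10)
})
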