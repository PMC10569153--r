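test_that("zero intensity yields an empty table and sampling is seed-deterministic", {
  geom <- circle_geometry(radius = 2000)
  empty <- flat_archetype(lambda = 0)
  expect_equal(nrow(sample_cells(empty, geom, seed = 1)), 0)
  arch <- flat_archetype(lambda = 50)
  c1 <- sample_cells(arch, geom, seed = 7)
  c2 <- sample_cells(arch, geom, seed = 7)
  expect_identical(c1, c2)
  expect_gt(nrow(c1), 0)
  # negative intensities are rejected at spec construction
  bad <- tibble::tibble(subset = "x", base_in = -5, base_out = 10, mid = 0,
                        slope = 30, bump = 0, bump_center = 0, bump_sd = 100)
  expect_error(archetype_spec("bad", bad), "non-negative")
})

test_that("constant-intensity counts are Poisson with mean lambda * area", {
  # lambda = 100 cells/mm^2 over a 14 x 14 mm extent
  geom <- circle_geometry(radius = 2000)
  arch <- flat_archetype(lambda = 100)
  n <- nrow(sample_cells(arch, geom, seed = 123, resolution = 20))
  mu <- 100 * 14^2
  expect_lt(abs(n - mu), 3 * sqrt(mu) * 1.2)
  # region-level: count inside a 10 mm^2 disc within 3 sd of 1000
  cells <- sample_cells(arch, geom, seed = 321, resolution = 20)
  r_disc <- sqrt(10 / pi) * 1000
  inside <- (cells$x_um - 7000)^2 + (cells$y_um - 7000)^2 <= r_disc^2
  expect_lt(abs(sum(inside) - 1000), 3 * sqrt(1000))
})

test_that("liver-like profiles put more CD8 at the outer margin than the core", {
  arch <- archetype_preset("liver_like")
  # by construction of the generating profile
  expect_gt(lambda_profile(arch, "cd8_t", 250), lambda_profile(arch, "cd8_t", -1000))
  geom <- make_geometry(extent_um = 13200, tumor_radius_um = 1200, seed = 1)
  fld <- distance_field(geom, resolution = 20)
  ar <- band_areas(geom, resolution = 20, field = fld)
  for (s in 0:4) {
    cells <- sample_cells(arch, geom, seed = s, field = fld)
    cd8 <- cells[cells$truth_subset == "cd8_t", ]
    b <- assign_band(signed_distance(cd8, geom, method = "raster", field = fld))
    dens <- table(b) / setNames(ar$area_mm2, as.character(ar$band))[names(table(b))]
    expect_gt(dens[["outer_margin"]], dens[["core"]])
  }
})

test_that("planted aggregates land in the requested band with the right composition", {
  geom <- make_geometry(extent_um = 15000, tumor_radius_um = 2000, seed = 2)
  spec <- archetype_spec("agg", flat_archetype(0)$profiles,
                         aggregates = list(
                           n = 5L, band_weights = c(outer_margin = 1),
                           cells_per_aggregate = 200L, sigma_um = 40,
                           composition = c(b_cell = 0.6, cd4_t = 0.4),
                           gc_fraction = 0.1, pd1_fraction = 0.3))
  out <- plant_aggregates(spec, geom, seed = 3)
  expect_equal(nrow(out$truth), 5)
  expect_equal(nrow(out$cells), 5 * 200)
  # recomputed centroid signed distances lie in the outer margin [0, 500)
  cen <- vapply(seq_len(5), function(i) {
    m <- out$cells[out$cells$truth_aggregate_id == i, ]
    signed_distance(cbind(mean(m$x_um), mean(m$y_um)), geom)
  }, numeric(1))
  expect_true(all(cen > -3 * 40 / sqrt(200) - 20 & cen < 500 + 3 * 40))
  # member labels within exact binomial 99% bounds at n = 200, p = 0.6
  for (i in 1:5) {
    nb <- sum(out$cells$truth_subset[out$cells$truth_aggregate_id == i] == "b_cell")
    bounds <- qbinom(c(0.005, 0.995), 200, 0.6)
    expect_gte(nb, bounds[1]); expect_lte(nb, bounds[2])
  }
  # zero aggregates -> empty truth
  none <- plant_aggregates(flat_archetype(0), geom, seed = 1)
  expect_equal(nrow(none$cells), 0)
  expect_equal(nrow(none$truth), 0)
  # weight on a band the geometry cannot host -> error
  small <- archetype_spec("agg2", flat_archetype(0)$profiles,
                          aggregates = list(
                            n = 1L, band_weights = c(distal = 1),
                            cells_per_aggregate = 10L, sigma_um = 40,
                            composition = c(b_cell = 1), gc_fraction = 0,
                            pd1_fraction = 0))
  tight <- tissue_geometry(circle_polygon(1000, c(2000, 2000)), c(0, 4000, 0, 4000))
  expect_error(plant_aggregates(small, tight, seed = 1), "absent")
})

test_that("intensity emission is thresholdable back to ground truth", {
  cells <- cells_at(1:50 * 10, rep(0, 50), subset = "cd8_t")
  cells$truth_subset <- rep(c("cd8_t", "b_cell"), 25)
  cells <- truth_markers_deterministic(cells[, c("cell_id", "x_um", "y_um", "truth_subset")])
  # zero-variance, means 0/10, threshold 5: thresholding reproduces truth exactly
  spec0 <- default_marker_noise(mu_neg = 0, sd_neg = 1e-12, mu_pos = 10, sd_pos = 1e-12)
  out <- emit_intensities(cells, spec0, seed = 1)
  called <- threshold_markers(out, setNames(rep(5, nrow(spec0)), spec0$marker))
  expect_equal(called$CD3, cells$CD3)
  expect_equal(called$CD20, cells$CD20)
  # missing spec for a used marker errors by name
  expect_error(emit_intensities(cells, spec0[spec0$marker != "CD3", ]), "CD3")
  # unknown marker in the spec errors
  bad <- dplyr::bind_rows(spec0, tibble::tibble(marker = "CD999", mu_neg = 0,
                                                sd_neg = 1, mu_pos = 5, sd_pos = 1))
  expect_error(emit_intensities(cells, bad), "CD999")
})

test_that("overlapping intensity distributions misclassify at about the analytic rate", {
  n <- 10000
  cells <- tibble::tibble(cell_id = as.character(1:n), x_um = runif(n, 0, 1000),
                          y_um = runif(n, 0, 1000),
                          truth_subset = rep(c("cd8_t", "other"), n / 2))
  cells <- truth_markers_deterministic(cells)
  spec <- default_marker_noise("CD3", mu_neg = 2, sd_neg = 1.5, mu_pos = 5, sd_pos = 1.5)
  out <- emit_intensities(cells[, c("cell_id", "x_um", "y_um", "truth_subset", "CD3")],
                          spec, seed = 0)
  called <- threshold_markers(out, c(CD3 = 3.5))
  err <- mean(called$CD3 != cells$CD3)
  analytic <- 0.5 * pnorm(3.5, 5, 1.5) + 0.5 * (1 - pnorm(3.5, 2, 1.5))
  expect_lt(err, 2 * analytic)
  expect_gt(err, analytic / 3)  # noise really is present
})

test_that("simulate_tissue is bit-identical under spec + seed and flags aggregate truth", {
  t1 <- simulate_tissue("peritoneal_like", seed = 9, resolution = 20,
                        extent_um = 13200, tumor_radius_um = 1200)
  t2 <- simulate_tissue("peritoneal_like", seed = 9, resolution = 20,
                        extent_um = 13200, tumor_radius_um = 1200)
  expect_identical(t1$cells, t2$cells)
  expect_identical(t1$geometry$tumor[[1]], t2$geometry$tumor[[1]])
  # every cell lies within the extent
  ext <- t1$geometry$extent
  expect_true(all(t1$cells$x_um >= ext[1] & t1$cells$x_um <= ext[2]))
  expect_true(all(t1$cells$y_um >= ext[3] & t1$cells$y_um <= ext[4]))
  # planted members are flagged
  expect_equal(sum(!is.na(t1$cells$truth_aggregate_id)),
               sum(t1$truth$aggregates$n_cells))
})
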