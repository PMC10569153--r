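# clustered lymphocytes around given centres
planted_clusters <- function(centres, n_each = 200, sigma = 40, seed = 1,
                             b_frac = 0.5, gc_frac = 0) {
  set.seed(seed)
  parts <- lapply(seq_len(nrow(centres)), function(i) {
    subs <- sample(c("b_cell", "cd4_t"), n_each, replace = TRUE,
                   prob = c(b_frac, 1 - b_frac))
    tibble::tibble(x_um = rnorm(n_each, centres[i, 1], sigma),
                   y_um = rnorm(n_each, centres[i, 2], sigma),
                   truth_subset = subs, truth_id = i)
  })
  cells <- dplyr::bind_rows(parts)
  cells$cell_id <- sprintf("c%05d", seq_len(nrow(cells)))
  cells <- truth_markers_deterministic(cells)
  if (gc_frac > 0) {
    b <- which(cells$truth_subset == "b_cell")
    cells$BCL6[sample(b, round(gc_frac * length(b)))] <- TRUE
  }
  cells
}

test_that("sparse uniform lymphocytes yield no aggregates", {
  for (seed in 0:4) {
    set.seed(seed)
    # mean spacing ~ 450 um >> eps = 50 um
    cells <- cells_at(runif(50, 0, 3000), runif(50, 0, 3000), subset = "b_cell")
    las <- detect_aggregates(cells, eps_um = 50, min_cells = 20)
    expect_equal(nrow(las$aggregates), 0)
    expect_true(all(las$cells$aggregate_id == 0L, na.rm = TRUE))
  }
})

test_that("well-separated planted clusters are recovered one-to-one", {
  centres <- cbind(c(1000, 1000, 4000, 4000, 7000), c(1000, 4000, 1000, 4000, 2500))
  cells <- planted_clusters(centres, n_each = 200, sigma = 40, seed = 2)
  las <- detect_aggregates(cells, eps_um = 50, min_cells = 20)
  expect_equal(nrow(las$aggregates), 5)
  # membership >= 95% correct by majority-overlap matching
  assigned <- las$cells$aggregate_id
  acc <- vapply(1:5, function(i) {
    got <- assigned[cells$truth_id == i]
    best <- names(which.max(table(got[got > 0])))
    mean(got == as.integer(best))
  }, numeric(1))
  expect_true(all(acc >= 0.95))
  # determinism: identical input -> identical clustering
  las2 <- detect_aggregates(cells, eps_um = 50, min_cells = 20)
  expect_identical(las$cells$aggregate_id, las2$cells$aggregate_id)
})

test_that("clusters closer than eps merge into one aggregate", {
  centres <- cbind(c(1000, 1030), c(1000, 1000))  # separation < eps
  cells <- planted_clusters(centres, n_each = 150, sigma = 20, seed = 3)
  las <- detect_aggregates(cells, eps_um = 50, min_cells = 20)
  expect_equal(nrow(las$aggregates), 1)
  expect_gte(las$aggregates$n_cells, 290)
})

test_that("maturity requires both germinal-centre BCL6 and a B-cell follicle", {
  # no BCL6 -> LA, regardless of size
  centres <- cbind(2000, 2000)
  no_gc <- planted_clusters(centres, n_each = 300, seed = 4, gc_frac = 0)
  las1 <- detect_aggregates(no_gc, eps_um = 50, min_cells = 20)
  expect_equal(as.character(las1$aggregates$maturity), "LA")
  # 50 BCL6+ of ~300 members with B fraction ~0.5 -> mature TLS
  with_gc <- planted_clusters(centres, n_each = 300, seed = 5, gc_frac = 0.4)
  las2 <- detect_aggregates(with_gc, eps_um = 50, min_cells = 20)
  expect_gte(las2$aggregates$n_bcl6, 10)
  expect_equal(as.character(las2$aggregates$maturity), "mature_TLS")
  # degenerate thresholds warn and classify everything mature
  expect_warning(rules0 <- maturity_rules(0, 0), "degenerate")
  relab <- classify_maturity(las1$aggregates, rules0)
  expect_true(all(relab$maturity == "mature_TLS"))
})

test_that("aggregate summaries count by centroid band and split areas consistently", {
  geom <- circle_geometry(radius = 2000)
  # one aggregate fully inside the core, one straddling the boundary
  centres <- cbind(c(7000, 9000), c(7000, 7000))
  cells <- planted_clusters(centres, n_each = 200, sigma = 40, seed = 6)
  map <- compartmentalize(assign_phenotype(cells), geom, resolution = 20)
  las <- detect_aggregates(map$cells, eps_um = 50, min_cells = 20)
  expect_equal(nrow(las$aggregates), 2)
  sm <- summarize_aggregates(las, map)
  expect_equal(sum(sm$per_band$n_aggregates), 2)
  expect_equal(sm$per_band$n_aggregates[sm$per_band$band == "core"], 1)
  expect_true(sm$intratumoral_presence)
  # straddling aggregate: split areas sum to its hull area within raster tolerance
  for (i in seq_len(nrow(sm$aggregates))) {
    split_sum <- sum(sm$split_areas$area_mm2[sm$split_areas$aggregate_id ==
                                               sm$aggregates$aggregate_id[i]])
    expect_equal(split_sum, sm$aggregates$area_mm2[i], tolerance = 0.05)
  }
  # boundary-straddling aggregate is counted once (in its centroid band)
  expect_equal(sum(sm$per_band$n_aggregates), nrow(las$aggregates))
})

test_that("sporadic densities drop only aggregate members", {
  geom <- circle_geometry(radius = 2000)
  centres <- cbind(7000, 7000)
  agg_cells <- planted_clusters(centres, n_each = 200, sigma = 40, seed = 7,
                                b_frac = 1)
  set.seed(8)
  bg <- cells_at(runif(100, 2500, 11500), runif(100, 2500, 11500),
                 subset = "cd8_t", id_prefix = "bg")
  cells <- dplyr::bind_rows(agg_cells, bg)
  cells$cell_id <- sprintf("c%05d", seq_len(nrow(cells)))
  map <- compartmentalize(assign_phenotype(cells), geom, resolution = 20)
  las <- detect_aggregates(map$cells, eps_um = 50, min_cells = 20)
  sp <- sporadic_densities(las, map)
  # all B cells are aggregated -> sporadic B density ~0 everywhere
  expect_true(all(sp$count[sp$subset == "b_cell"] <= 2))
  # with no aggregates the sporadic table equals the full table
  map_bg <- compartmentalize(assign_phenotype(bg), geom, resolution = 20)
  las_none <- detect_aggregates(map_bg$cells, eps_um = 50, min_cells = 20)
  expect_equal(sporadic_densities(las_none, map_bg)$count,
               density_table(map = map_bg)$count)
  # tidy/glance accessors
  td <- tidy(las)
  expect_true(all(c("aggregate_id", "n_cells", "area_mm2", "maturity") %in% names(td)))
  gl <- glance(las)
  expect_equal(gl$n_aggregates, nrow(las$aggregates))
})

test_that("cohort presence fraction reflects planted intratumoral aggregates", {
  geom <- circle_geometry(radius = 2000)
  present <- logical(10)
  for (k in 1:10) {
    centre <- if (k <= 4) cbind(7000, 7000) else cbind(12000, 12000)
    cells <- planted_clusters(centre, n_each = 120, sigma = 40, seed = 10 + k)
    map <- compartmentalize(assign_phenotype(cells), geom, resolution = 20)
    las <- detect_aggregates(map$cells, eps_um = 50, min_cells = 20)
    present[k] <- summarize_aggregates(las, map)$intratumoral_presence
  }
  expect_equal(mean(present) * 100, 40)
})
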