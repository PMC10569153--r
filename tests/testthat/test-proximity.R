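test_that("neighbor counts use an inclusive radius and exclude self-pairs", {
  src <- tibble::tibble(cell_id = "s1", x_um = 0, y_um = 0)
  tgt <- tibble::tibble(cell_id = c("t1", "t2", "t3"),
                        x_um = c(0, 0, 0), y_um = c(6, 10, 10.5))
  expect_equal(neighbor_counts(src, tgt, r = 10), 2L)  # boundary inclusive
  # no targets -> all zero
  expect_equal(neighbor_counts(src, tgt[0, ], r = 10), 0L)
  # shared cells are never their own neighbor
  both <- tibble::tibble(cell_id = c("a", "b"), x_um = c(0, 5), y_um = c(0, 0))
  expect_equal(neighbor_counts(both, both, r = 10), c(1L, 1L))
})

test_that("grid counts match the all-pairs brute-force oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    ns <- 500; nt <- 500
    src <- tibble::tibble(cell_id = paste0("s", 1:ns),
                          x_um = runif(ns, 0, 2000), y_um = runif(ns, 0, 2000))
    tgt <- tibble::tibble(cell_id = paste0("t", 1:nt),
                          x_um = runif(nt, 0, 2000), y_um = runif(nt, 0, 2000))
    expect_identical(neighbor_counts(src, tgt, r = 30),
                     neighbor_counts(src, tgt, r = 30, method = "brute"))
  }
})

test_that("proximity statistics are translation and rotation invariant", {
  set.seed(4)
  src <- tibble::tibble(cell_id = paste0("s", 1:200),
                        x_um = runif(200, 0, 1000), y_um = runif(200, 0, 1000))
  tgt <- tibble::tibble(cell_id = paste0("t", 1:200),
                        x_um = runif(200, 0, 1000), y_um = runif(200, 0, 1000))
  base <- neighbor_counts(src, tgt, r = 25)
  shift <- function(df, dx, dy) dplyr::mutate(df, x_um = x_um + dx, y_um = y_um + dy)
  expect_identical(neighbor_counts(shift(src, 500, -300), shift(tgt, 500, -300), 25), base)
  rot <- function(df, a) dplyr::mutate(df,
    x0 = x_um * cos(a) - y_um * sin(a), y0 = x_um * sin(a) + y_um * cos(a),
    x_um = x0, y_um = y0)
  expect_identical(neighbor_counts(rot(src, 0.7), rot(tgt, 0.7), 25), base)
})

test_that("mean neighbors and contact fraction are monotone in the radius", {
  set.seed(5)
  src <- tibble::tibble(cell_id = paste0("s", 1:300),
                        x_um = runif(300, 0, 1500), y_um = runif(300, 0, 1500))
  tgt <- tibble::tibble(cell_id = paste0("t", 1:300),
                        x_um = runif(300, 0, 1500), y_um = runif(300, 0, 1500))
  radii <- c(5, 10, 20, 40, 80)
  means <- vapply(radii, function(r) mean(neighbor_counts(src, tgt, r)), numeric(1))
  fracs <- vapply(radii, function(r) mean(neighbor_counts(src, tgt, r) > 0), numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_true(all(diff(fracs) >= 0))
})

test_that("mutual availability reports both directions per band with symmetry", {
  geom <- circle_geometry(radius = 2000)
  # symmetric planted pairs at 5 um spacing inside the core
  n <- 40
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ax <- 7000 + 800 * cos(ang); ay <- 7000 + 800 * sin(ang)
  apc <- cells_at(ax, ay, subset = "apc", id_prefix = "a")
  t8 <- cells_at(ax + 5, ay, subset = "cd8_stem", id_prefix = "t")
  cells <- dplyr::bind_rows(apc, t8)
  cells$cell_id <- sprintf("c%04d", seq_len(nrow(cells)))
  map <- compartmentalize(assign_phenotype(cells), geom, resolution = 20)
  av <- mutual_availability(map = map, source = "apc", target = "cd8_stem", r = 10)
  core_fwd <- av[av$band == "core" & av$source == "apc", ]
  core_rev <- av[av$band == "core" & av$source == "cd8_stem", ]
  expect_equal(core_fwd$mean_neighbors, 1)
  expect_equal(core_rev$mean_neighbors, 1)
  # pair-count symmetry: sum of counts equals sum of reverse counts
  expect_equal(core_fwd$mean_neighbors * core_fwd$n_source,
               core_rev$mean_neighbors * core_rev$n_source)
  # empty bands are missing
  expect_true(is.na(av$mean_neighbors[av$band == "distal" & av$source == "apc"]))
})

test_that("contact stats match the planted configuration and Poisson voids", {
  geom <- circle_geometry(radius = 2000)
  n <- 30
  ax <- seq(6500, 7500, length.out = n)
  apc <- cells_at(ax, rep(7000, n), subset = "apc", id_prefix = "a")
  t8 <- cells_at(ax, rep(7002, n), subset = "cd8_stem", id_prefix = "t")
  cells <- dplyr::bind_rows(apc, t8)
  cells$cell_id <- sprintf("c%04d", seq_len(nrow(cells)))
  map <- compartmentalize(assign_phenotype(cells), geom, resolution = 20)
  cs <- contact_stats(map = map, source = "apc", target = "cd8_stem", r = 10)
  core <- cs[cs$band == "core", ]
  expect_equal(core$contact_fraction, 100)
  expect_equal(core$mean_nn_um, 2)
  # targets beyond r: contact fraction 0, NN distance still finite
  far <- dplyr::mutate(t8, y_um = y_um + 500)
  cells2 <- dplyr::bind_rows(apc, far)
  cells2$cell_id <- sprintf("c%04d", seq_len(nrow(cells2)))
  map2 <- compartmentalize(assign_phenotype(cells2), geom, resolution = 20)
  cs2 <- contact_stats(map = map2, source = "apc", target = "cd8_stem", r = 10)
  core2 <- cs2[cs2$band == "core", ]
  expect_equal(core2$contact_fraction, 0)
  expect_equal(core2$mean_nn_um, 502, tolerance = 1e-6)
  # Poisson targets at intensity rho: contact fraction ~ 100 (1 - exp(-rho pi r^2))
  set.seed(6)
  rho <- 400 / 1e6  # 400 cells/mm^2 in um^-2
  box <- 3000
  ntg <- rpois(1, rho * box^2)
  tgt <- cells_at(runif(ntg, 5500, 8500), runif(ntg, 5500, 8500),
                  subset = "cd8_stem", id_prefix = "t")
  srcp <- cells_at(runif(400, 6500, 7500), runif(400, 6500, 7500),
                   subset = "apc", id_prefix = "a")
  cells3 <- dplyr::bind_rows(srcp, tgt)
  cells3$cell_id <- sprintf("c%05d", seq_len(nrow(cells3)))
  map3 <- compartmentalize(assign_phenotype(cells3), geom, resolution = 20)
  cs3 <- contact_stats(map = map3, source = "apc", target = "cd8_stem", r = 10)
  obs <- sum(cs3$contact_fraction * cs3$n_source, na.rm = TRUE) / sum(cs3$n_source)
  expected <- 100 * (1 - exp(-rho * pi * 100))
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / 400)
  expect_lt(abs(obs - expected), 4 * se)
})
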