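#' Generate a tumor-boundary geometry
#'
#' Builds a smooth, star-shaped (hence simple) tumor polygon from a Fourier
#' perturbation of a circle, optional circular necrosis pockets inside it, and
#' a square tissue extent. The extent must leave at least the distal cutoff
#' (5 mm) of tissue outside the tumor boundary so all five bands exist.
#'
#' @param extent_um Side length of the square extent (um), or a length-4
#'   vector `c(xmin, xmax, ymin, ymax)`.
#' @param tumor_radius_um Mean tumor radius (um).
#' @param irregularity Relative amplitude of the boundary perturbation.
#' @param n_vertices Polygon vertex count.
#' @param necrosis Optional list of `list(center = c(x, y), radius = r)`
#'   discs (um) carved as necrosis polygons.
#' @param required_margin_um Minimum tissue margin outside the tumor (um).
#' @param seed Integer seed controlling the boundary shape.
#' @return A [tissue_geometry()].
#' @export
make_geometry <- function(extent_um = 15000, tumor_radius_um = 2000,
                          irregularity = 0.12, n_vertices = 64,
                          necrosis = NULL, required_margin_um = 5000,
                          seed = 1) {
  extent <- if (length(extent_um) == 1) c(0, extent_um, 0, extent_um) else as.numeric(extent_um)
  cx <- mean(extent[1:2]); cy <- mean(extent[3:4])
  poly <- with_seed(seed, {
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    amp <- stats::runif(4, 0, irregularity / 4)  # sum bounded by irregularity
    phase <- stats::runif(4, 0, 2 * pi)
    r <- tumor_radius_um * (1 + Reduce(`+`, lapply(1:4, function(k) {
      amp[k] * cos((k + 1) * theta + phase[k])
    })))
    cbind(cx + r * cos(theta), cy + r * sin(theta))
  })
  rmax <- max(sqrt((poly[, 1] - cx)^2 + (poly[, 2] - cy)^2))
  margin <- min(cx - extent[1], extent[2] - cx, cy - extent[3], extent[4] - cy) - rmax
  if (margin < required_margin_um) {
    rlang::abort(sprintf(
      "extent too small: only %.0f um of tissue outside the tumor boundary; >= %.0f um required to host the distal band",
      margin, required_margin_um))
  }
  nec <- lapply(necrosis %||% list(), function(h) {
    theta <- seq(0, 2 * pi, length.out = 33)[-33]
    cbind(h$center[1] + h$radius * cos(theta), h$center[2] + h$radius * sin(theta))
  })
  tissue_geometry(poly, extent, necrosis = nec)
}

#' Sample background cells from an archetype
#'
#' Inhomogeneous Poisson sampling of every subset's intensity profile over the
#' signed-distance field: a homogeneous Poisson process at the profile maximum
#' is thinned by lambda(d(x)) / lambda_max, so counts in any region are
#' Poisson with mean equal to the integral of lambda over the region (up to
#' raster error in d).
#'
#' @param spec An `archetype_spec`.
#' @param geometry A [tissue_geometry()].
#' @param seed Integer seed.
#' @param resolution Raster resolution (um) of the signed-distance lookup.
#' @param field Optional precomputed [distance_field()].
#' @return Tibble of cells: `x_um`, `y_um`, `truth_subset`.
#' @export
sample_cells <- function(spec, geometry, seed = 1, resolution = 10,
                         field = NULL) {
  fld <- field %||% distance_field(geometry, resolution)
  ext <- geometry$extent
  area_mm2 <- (ext[2] - ext[1]) * (ext[4] - ext[3]) / 1e6
  drange <- range(fld$d)
  dgrid <- seq(drange[1], drange[2], length.out = 4096)
  with_seed(seed, {
    parts <- lapply(spec$profiles$subset, function(s) {
      lam_grid <- lambda_profile(spec, s, dgrid)
      if (any(lam_grid < 0)) rlang::abort("negative intensity encountered")
      lmax <- max(lam_grid) * (1 + 1e-9)
      if (lmax <= 0) return(NULL)
      n_cand <- stats::rpois(1, lmax * area_mm2)
      if (!n_cand) return(NULL)
      x <- stats::runif(n_cand, ext[1], ext[2])
      y <- stats::runif(n_cand, ext[3], ext[4])
      lam <- lambda_profile(spec, s, lookup_field(fld, x, y))
      keep <- stats::runif(n_cand) < lam / lmax
      if (!any(keep)) return(NULL)
      tibble::tibble(x_um = x[keep], y_um = y[keep], truth_subset = s)
    })
    dplyr::bind_rows(parts)
  })
}

#' Plant clustered lymphoid aggregates
#'
#' Thomas-style cluster process: aggregate centres are placed in bands drawn
#' from the archetype's band weights, members are Gaussian-displaced
#' (`sigma_um`) around each centre with subset labels drawn from the
#' composition fractions, and each aggregate's convex hull is recorded as
#' ground truth. B-cell members acquire BCL6 positivity (germinal centre)
#' with probability `gc_fraction`.
#'
#' @inheritParams sample_cells
#' @return List with `cells` (tibble incl. `truth_aggregate_id`, `gc` flag)
#'   and `truth` (tibble: `truth_aggregate_id`, `band`, `center_x`,
#'   `center_y`, `n_cells`, `polygon` list-column).
#' @export
plant_aggregates <- function(spec, geometry, seed = 1, resolution = 10,
                             field = NULL) {
  agg <- spec$aggregates
  empty <- list(cells = tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                                       truth_subset = character(0),
                                       truth_aggregate_id = integer(0),
                                       gc = logical(0)),
                truth = tibble::tibble(truth_aggregate_id = integer(0),
                                       band = character(0), center_x = numeric(0),
                                       center_y = numeric(0), n_cells = integer(0),
                                       polygon = list()))
  if (agg$n == 0) return(empty)
  fld <- field %||% distance_field(geometry, resolution)
  present <- unique(as.character(assign_band(as.vector(fld$d))))
  absent <- setdiff(names(agg$band_weights)[agg$band_weights > 0], present)
  if (length(absent)) {
    rlang::abort(paste0("aggregate band weight on band(s) absent from the geometry: ",
                        paste(absent, collapse = ", ")))
  }
  ext <- geometry$extent
  with_seed(seed, {
    cells <- list(); truth <- list()
    for (i in seq_len(agg$n)) {
      target_band <- sample(names(agg$band_weights), 1, prob = agg$band_weights)
      center <- NULL
      for (try in 1:20000) {
        cx <- stats::runif(1, ext[1], ext[2]); cy <- stats::runif(1, ext[3], ext[4])
        b <- as.character(assign_band(lookup_field(fld, cx, cy)))
        if (b == target_band) { center <- c(cx, cy); break }
      }
      if (is.null(center)) rlang::abort("could not place an aggregate centre in the requested band")
      n <- agg$cells_per_aggregate
      x <- pmin(ext[2], pmax(ext[1], stats::rnorm(n, center[1], agg$sigma_um)))
      y <- pmin(ext[4], pmax(ext[3], stats::rnorm(n, center[2], agg$sigma_um)))
      subs <- sample(names(agg$composition), n, replace = TRUE, prob = agg$composition)
      gc <- subs == "b_cell" & stats::runif(n) < agg$gc_fraction
      cells[[i]] <- tibble::tibble(x_um = x, y_um = y, truth_subset = subs,
                                   truth_aggregate_id = i, gc = gc)
      hull_idx <- grDevices::chull(x, y)
      truth[[i]] <- tibble::tibble(truth_aggregate_id = i, band = target_band,
                                   center_x = center[1], center_y = center[2],
                                   n_cells = n,
                                   polygon = list(cbind(x, y)[hull_idx, , drop = FALSE]))
    }
    list(cells = dplyr::bind_rows(cells), truth = dplyr::bind_rows(truth))
  })
}

# Boolean ground-truth marker columns from terminal subset labels.
truth_marker_calls <- function(cells, functional = list(pd1 = 0.15, pdl1 = 0.2),
                               pd1_aggregate = NULL) {
  lm <- leaf_markers()
  for (m in all_markers()) cells[[m]] <- FALSE
  for (leaf in names(lm)) {
    rows <- cells$truth_subset == leaf
    for (m in lm[[leaf]]) cells[[m]][rows] <- TRUE
  }
  if ("gc" %in% names(cells)) cells$BCL6 <- cells$BCL6 | cells$gc
  t_or_b <- cells$truth_subset %in% c("treg", "tfh", "cd4_activated", "cd4_tcf1",
                                      "cd8_activated", "cd8_stem", "cd4_t",
                                      "cd8_t", "gd_t", "b_cell")
  myeloid <- cells$truth_subset %in% c("m1_tam", "m2_tam", "tan")
  p_pd1 <- rep(functional$pd1, nrow(cells))
  if (!is.null(pd1_aggregate) && "truth_aggregate_id" %in% names(cells)) {
    p_pd1[!is.na(cells$truth_aggregate_id)] <- pd1_aggregate
  }
  cells$PD1 <- t_or_b & stats::runif(nrow(cells)) < p_pd1
  cells$PDL1 <- myeloid & stats::runif(nrow(cells)) < functional$pdl1
  cells
}

#' Emit continuous marker intensities
#'
#' Adds a `<marker>_int` column per marker: positives draw from the marker's
#' positive intensity distribution, negatives from the negative one, so the
#' boolean truth is recoverable by thresholding with an error rate governed
#' by the distribution overlap.
#'
#' @param cells Cell table with logical marker columns.
#' @param noise_spec Tibble from [default_marker_noise()].
#' @param seed Integer seed.
#' @return `cells` with intensity columns added.
#' @export
emit_intensities <- function(cells, noise_spec = default_marker_noise(), seed = 1) {
  unknown <- setdiff(noise_spec$marker, names(cells))
  if (length(unknown)) {
    rlang::abort(paste0("unknown marker(s) in noise spec: ",
                        paste(unknown, collapse = ", ")))
  }
  used <- intersect(all_markers(), names(cells))
  missing <- setdiff(used, noise_spec$marker)
  if (length(missing)) {
    rlang::abort(paste0("marker(s) without a noise spec: ",
                        paste(missing, collapse = ", ")))
  }
  with_seed(seed, {
    for (i in seq_len(nrow(noise_spec))) {
      m <- noise_spec$marker[i]
      pos <- as.logical(cells[[m]])
      v <- numeric(nrow(cells))
      v[pos] <- stats::rnorm(sum(pos), noise_spec$mu_pos[i], noise_spec$sd_pos[i])
      v[!pos] <- stats::rnorm(sum(!pos), noise_spec$mu_neg[i], noise_spec$sd_neg[i])
      cells[[paste0(m, "_int")]] <- v
    }
    cells
  })
}

#' Simulate a complete synthetic tissue
#'
#' Composes [make_geometry()], [sample_cells()], [plant_aggregates()] and
#' ground-truth marker calls into one reproducible sample. All randomness
#' derives from the single integer `seed`; identical spec + seed yields a
#' bit-identical cell table.
#'
#' @param spec An `archetype_spec` (or preset name).
#' @param seed Integer seed.
#' @param geometry Optional [tissue_geometry()]; made from `...` otherwise.
#' @param resolution Raster resolution (um) for the signed-distance field.
#' @param intensities Also emit continuous marker intensities.
#' @param sample_id Sample label stored in the cell table.
#' @param ... Passed to [make_geometry()].
#' @return A `synthetic_tissue`: list with `geometry`, `cells` (cell_id,
#'   coordinates, boolean markers, `truth_subset`, `truth_aggregate_id`),
#'   `truth` (planted aggregate polygons, the archetype, seed), and `field`.
#' @export
simulate_tissue <- function(spec, seed = 1, geometry = NULL, resolution = 10,
                            intensities = FALSE, sample_id = NULL, ...) {
  if (is.character(spec)) spec <- archetype_preset(spec)
  geometry <- geometry %||% make_geometry(seed = child_seed(seed, 1), ...)
  fld <- distance_field(geometry, resolution)
  bg <- sample_cells(spec, geometry, seed = child_seed(seed, 2), field = fld)
  ag <- plant_aggregates(spec, geometry, seed = child_seed(seed, 3), field = fld)
  bg$truth_aggregate_id <- rep(NA_integer_, nrow(bg))
  bg$gc <- rep(FALSE, nrow(bg))
  cells <- dplyr::bind_rows(bg, ag$cells)
  cells <- with_seed(child_seed(seed, 4),
                     truth_marker_calls(cells, spec$functional,
                                        pd1_aggregate = spec$aggregates$pd1_fraction))
  if (intensities) {
    cells <- emit_intensities(cells, spec$marker_noise, seed = child_seed(seed, 5))
  }
  cells <- dplyr::mutate(cells,
                         cell_id = sprintf("c%06d", dplyr::row_number()),
                         sample_id = sample_id %||% sprintf("%s_s%d", spec$name, seed),
                         .before = 1)
  structure(list(geometry = geometry, cells = cells,
                 truth = list(aggregates = ag$truth, spec = spec, seed = seed),
                 field = fld),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("<synthetic_tissue> '%s' seed %d: %d cells, %d planted aggregate(s)\n",
              x$truth$spec$name, x$truth$seed, nrow(x$cells),
              nrow(x$truth$aggregates)))
  invisible(x)
}

#' Simulate a cohort of tissues
#'
#' @param spec Archetype spec or preset name.
#' @param n_samples Number of tissues.
#' @param seed Integer master seed; sample i uses a derived child seed.
#' @param ... Passed to [simulate_tissue()].
#' @return List of `synthetic_tissue` objects.
#' @export
simulate_cohort <- function(spec, n_samples, seed = 1, ...) {
  if (is.character(spec)) spec <- archetype_preset(spec)
  lapply(seq_len(n_samples), function(i) {
    simulate_tissue(spec, seed = child_seed(seed, 100 + i),
                    sample_id = sprintf("%s_%02d", spec$name, i), ...)
  })
}
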