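#' Histologic band labels used throughout the package
#'
#' The five analysis compartments defined by signed distance d (um) to the
#' tumor boundary, plus the 2-5 mm `buffer` zone that separates the
#' juxtatumoral band from distal tissue and is excluded from five-band tables:
#' `core` (d < -500), `inner_margin` (-500 <= d < 0), `outer_margin`
#' (0 <= d < 500), `juxta` (500 <= d < 2000), `buffer` (2000 <= d < 5000),
#' `distal` (d >= 5000).
#'
#' @param include_buffer Include `"buffer"` in the returned level set.
#' @return Character vector of band levels, ordered from tumor core outward.
#' @export
band_levels <- function(include_buffer = TRUE) {
  lv <- c("core", "inner_margin", "outer_margin", "juxta", "buffer", "distal")
  if (!include_buffer) lv <- setdiff(lv, "buffer")
  lv
}

#' Assign signed distances to histologic bands
#'
#' Pure function of signed distance. Intervals are half-open with the tumor
#' boundary (d = 0) assigned to the outer invasive margin, so every finite
#' distance receives exactly one band.
#'
#' @param d Signed distances in um (negative inside the tumor).
#' @param cutoffs Band cutoffs in um, strictly increasing: margin half-width,
#'   juxtatumoral limit, distal start. Defaults `c(500, 2000, 5000)`.
#' @param merge_buffer If `TRUE`, extend `distal` down to the juxtatumoral
#'   limit (no buffer zone).
#' @return Factor of band labels with levels from [band_levels()].
#' @export
assign_band <- function(d, cutoffs = c(500, 2000, 5000), merge_buffer = FALSE) {
  stopifnot(length(cutoffs) == 3, all(diff(cutoffs) > 0), all(cutoffs > 0))
  if (any(!is.finite(d))) rlang::abort("signed distances must be finite")
  out <- character(length(d))
  out[d < -cutoffs[1]] <- "core"
  out[d >= -cutoffs[1] & d < 0] <- "inner_margin"
  out[d >= 0 & d < cutoffs[1]] <- "outer_margin"
  out[d >= cutoffs[1] & d < cutoffs[2]] <- "juxta"
  out[d >= cutoffs[2] & d < cutoffs[3]] <- if (merge_buffer) "distal" else "buffer"
  out[d >= cutoffs[3]] <- "distal"
  factor(out, levels = band_levels())
}

#' Band areas from the raster distance field
#'
#' Areas (mm^2) of each band within the tissue extent, from pixel counts at the
#' stated raster resolution. The distal band is always clipped by the extent;
#' if even the buffer zone is truncated (extent margin < distal cutoff), a
#' warning notes the clipping.
#'
#' @inheritParams signed_distance
#' @inheritParams assign_band
#' @param resolution Raster resolution, um/pixel.
#' @param field Optional precomputed [distance_field()].
#' @return Tibble with `band`, `area_mm2`.
#' @export
band_areas <- function(geometry, resolution = 10, cutoffs = c(500, 2000, 5000),
                       merge_buffer = FALSE, field = NULL) {
  stopifnot(resolution > 0)
  fld <- field %||% distance_field(geometry, resolution)
  bands <- assign_band(as.vector(fld$d), cutoffs, merge_buffer)
  px_mm2 <- fld$resolution^2 / 1e6
  counts <- table(bands)
  if (max(fld$d) < cutoffs[3]) {
    rlang::warn(sprintf(
      "extent truncates the band structure before the distal cutoff (max d = %.0f um); clipped areas reported",
      max(fld$d)))
  }
  tibble::tibble(band = factor(names(counts), levels = band_levels()),
                 area_mm2 = as.numeric(counts) * px_mm2)
}

#' Compartmentalize a cell table
#'
#' Computes per-cell signed distance to the tumor boundary, assigns the five
#' histologic bands (+ buffer), computes per-band areas, and optionally
#' classifies intratumoral tissue subregions. This is the per-sample
#' "regionize" stage.
#'
#' @param cells Cell table with `x_um`, `y_um` (and `subset` if subregions are
#'   requested).
#' @inheritParams signed_distance
#' @inheritParams assign_band
#' @param resolution Raster resolution (um/pixel) for areas and the raster
#'   distance path.
#' @param distance_method `"exact"` (default for <= `raster_threshold` cells)
#'   or `"raster"`; `"auto"` picks by size.
#' @param raster_threshold Cell count above which `"auto"` switches to the
#'   raster distance path.
#' @param subregions If `TRUE`, classify cancer island / stroma / necrosis
#'   within the tumor (requires phenotypes; see [classify_subregion()]).
#' @param field Optional precomputed [distance_field()] to reuse.
#' @param ... Passed to [classify_subregion()].
#' @return A `compartment_map`: list with `cells` (input plus `d_um`, `band`,
#'   and optionally `subregion`), `areas`, `cutoffs`, `resolution`, and the
#'   distance `field`.
#' @export
compartmentalize <- function(cells, geometry, cutoffs = c(500, 2000, 5000),
                             resolution = 10, merge_buffer = FALSE,
                             distance_method = c("auto", "exact", "raster"),
                             raster_threshold = 50000, subregions = FALSE,
                             field = NULL, ...) {
  distance_method <- rlang::arg_match(distance_method)
  assert_cols(cells, c("x_um", "y_um"), "cells")
  fld <- field %||% distance_field(geometry, resolution)
  method <- switch(distance_method,
                   auto = if (nrow(cells) > raster_threshold) "raster" else "exact",
                   distance_method)
  cells <- dplyr::mutate(tibble::as_tibble(cells),
                         d_um = signed_distance(cells, geometry, method = method,
                                                field = fld),
                         band = assign_band(.data$d_um, cutoffs, merge_buffer))
  areas <- band_areas(geometry, resolution, cutoffs, merge_buffer, field = fld)
  map <- structure(list(cells = cells, areas = areas, cutoffs = cutoffs,
                        resolution = resolution, merge_buffer = merge_buffer,
                        field = fld, geometry = geometry),
                   class = "compartment_map")
  if (subregions) map <- classify_subregion(map, geometry, ...)
  map
}

#' @export
print.compartment_map <- function(x, ...) {
  cat(sprintf("<compartment_map> %d cells, resolution %g um/px\n",
              nrow(x$cells), x$resolution))
  print(x$areas)
  invisible(x)
}

#' Classify intratumoral tissue subregions
#'
#' Splits the tumor interior (core + inner invasive margin) into the three
#' tissue classes: pixels inside declared necrosis polygons are `necrosis`;
#' elsewhere, pixels whose local tumor-cell count within the kernel radius
#' reaches the occupancy threshold are `cancer_island`, the remainder
#' `stroma`. Cells inherit the class of their pixel; cells outside the tumor
#' get `NA`.
#'
#' @param map A `compartment_map` from [compartmentalize()] whose cells carry a
#'   `subset` column with `"tumor"` labels.
#' @inheritParams signed_distance
#' @param kernel_radius_um Disc radius for local tumor-cell occupancy (um).
#' @param occupancy_threshold Minimum tumor cells per kernel disc for
#'   `cancer_island`.
#' @return The map with `subregion` added to `cells` and a `subregion_areas`
#'   tibble (mm^2, within core + inner margin).
#' @export
classify_subregion <- function(map, geometry = map$geometry,
                               kernel_radius_um = 50, occupancy_threshold = 20) {
  cells <- map$cells
  assert_cols(cells, c("subset", "d_um"), "cells")
  fld <- map$field
  res <- fld$resolution
  inside <- fld$d < 0
  tum <- cells[cells$subset == "tumor", ]
  if (!nrow(tum) && any(inside)) {
    rlang::warn("no tumor cells inside the boundary; all non-necrotic tumor tissue classified as stroma")
  }
  # tumor-cell counts per pixel, smoothed with a disc kernel
  nxp <- length(fld$xc); nyp <- length(fld$yc)
  counts <- matrix(0, nxp, nyp)
  if (nrow(tum)) {
    ix <- pmin(nxp, pmax(1L, as.integer(round((tum$x_um - fld$extent[1]) / res + 0.5))))
    iy <- pmin(nyp, pmax(1L, as.integer(round((tum$y_um - fld$extent[3]) / res + 0.5))))
    tab <- table(factor(ix, levels = 1:nxp), factor(iy, levels = 1:nyp))
    counts <- matrix(as.numeric(tab), nxp, nyp)
  }
  kr <- max(1L, as.integer(ceiling(kernel_radius_um / res)))
  off <- seq(-kr, kr)
  disc <- outer(off, off, function(a, b) as.numeric((a^2 + b^2) * res^2 <= kernel_radius_um^2))
  local <- as.matrix(EBImage::filter2(counts, disc, boundary = 0))
  subregion <- matrix(NA_character_, nxp, nyp)
  subregion[inside] <- ifelse(local[inside] >= occupancy_threshold, "cancer_island", "stroma")
  for (p in geometry$necrosis) {
    nec <- rasterize_polygon(p, fld$xc, fld$yc) & inside
    subregion[nec] <- "necrosis"
  }
  # cells inherit their pixel class
  ixc <- pmin(nxp, pmax(1L, as.integer(round((cells$x_um - fld$extent[1]) / res + 0.5))))
  iyc <- pmin(nyp, pmax(1L, as.integer(round((cells$y_um - fld$extent[3]) / res + 0.5))))
  cls <- subregion[cbind(ixc, iyc)]
  cells$subregion <- factor(cls, levels = subregion_levels())
  map$cells <- cells
  px_mm2 <- res^2 / 1e6
  tab <- table(factor(subregion[inside], levels = subregion_levels()))
  map$subregion_areas <- tibble::tibble(
    subregion = factor(names(tab), levels = subregion_levels()),
    area_mm2 = as.numeric(tab) * px_mm2)
  map$subregion_params <- list(kernel_radius_um = kernel_radius_um,
                               occupancy_threshold = occupancy_threshold)
  map
}

#' @rdname band_levels
#' @export
subregion_levels <- function() c("cancer_island", "stroma", "necrosis")
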