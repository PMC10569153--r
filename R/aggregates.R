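# Deterministic DBSCAN on um coordinates. A point is core when the number of
# points within eps, counting itself, reaches min_pts. Clusters are connected
# components of core points; border points join the cluster of their nearest
# core neighbor (ties -> lowest cluster id). Cluster ids are renumbered by
# smallest member row so identical input always yields identical labels.
dbscan_labels <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  if (!n) return(integer(0))
  pairs <- radius_pairs(xy, xy, eps)
  pairs <- pairs[pairs$si != pairs$ti, ]
  deg <- tabulate(pairs$si, nbins = n)
  core <- (deg + 1L) >= min_pts
  labels <- integer(n)
  if (!any(core)) return(labels)
  cp <- pairs[core[pairs$si] & core[pairs$ti], ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(cp$si), to = as.character(cp$ti)),
    directed = FALSE, vertices = data.frame(name = as.character(which(core))))
  comp <- igraph::components(g)
  labels[as.integer(igraph::V(g)$name)] <- comp$membership
  # border points: nearest core neighbor's cluster
  bp <- pairs[!core[pairs$si] & core[pairs$ti], ]
  if (nrow(bp)) {
    d <- sqrt((xy[bp$si, 1] - xy[bp$ti, 1])^2 + (xy[bp$si, 2] - xy[bp$ti, 2])^2)
    ord <- order(bp$si, d, labels[bp$ti])
    bp <- bp[ord, ]; first <- !duplicated(bp$si)
    labels[bp$si[first]] <- labels[bp$ti[first]]
  }
  # renumber deterministically by smallest member index
  ids <- sort(unique(labels[labels > 0]))
  firsts <- vapply(ids, function(k) min(which(labels == k)), integer(1))
  remap <- integer(max(ids)); remap[ids[order(firsts)]] <- seq_along(ids)
  labels[labels > 0] <- remap[labels[labels > 0]]
  labels
}

#' Detect lymphoid aggregates from lymphocyte coordinates
#'
#' Density-based clustering (DBSCAN; radius `eps`, minimum `min_cells`
#' neighbors counting the cell itself) over the T- and B-lymphocyte cells of a
#' gated table. Clusters smaller than `min_cells` are discarded; lymphocytes
#' outside any cluster are flagged sporadic. For each aggregate the convex
#' hull, area, centroid and lymphoid composition (B, CD4, CD8, Tfh, BCL6+
#' cells) are computed and maturity is classified (see [classify_maturity()]).
#'
#' @param cells Gated cell table with `x_um`, `y_um`, `subset` (marker columns
#'   used for composition when present).
#' @param eps_um Neighborhood radius in um.
#' @param min_cells Minimum neighborhood size and minimum aggregate size.
#' @param lymphocyte_subsets Subsets eligible for aggregation (default: T and
#'   B lineages).
#' @param config Gating config.
#' @param rules Maturity rules, see [classify_maturity()].
#' @return An `la_set`: list with `aggregates` (tibble; one row per aggregate
#'   with `hull` as a list-column of vertex matrices), `cells` (input with an
#'   `aggregate_id` column: the aggregate number for members, 0 for sporadic
#'   lymphocytes, `NA` for non-lymphocytes), and `params`.
#' @export
detect_aggregates <- function(cells, eps_um = 50, min_cells = 20,
                              lymphocyte_subsets = c("cd4_t", "cd8_t", "gd_t", "b_cell"),
                              config = default_gating_config(),
                              rules = maturity_rules()) {
  stopifnot(eps_um > 0, min_cells >= 3)
  cells <- tibble::as_tibble(cells)
  assert_cols(cells, c("x_um", "y_um"), "cells")
  memb <- membership_long(cells, config)
  lymph_rows <- sort(unique(memb$row[memb$subset %in% lymphocyte_subsets]))
  labels_all <- rep(NA_integer_, nrow(cells))
  if (length(lymph_rows)) {
    xy <- cbind(cells$x_um[lymph_rows], cells$y_um[lymph_rows])
    lab <- dbscan_labels(xy, eps_um, min_cells)
    sizes <- tabulate(lab)
    small <- which(sizes < min_cells)
    lab[lab %in% small] <- 0L
    keep <- sort(unique(lab[lab > 0]))
    lab <- match(lab, keep, nomatch = 0L)  # compact ids, order preserved
    labels_all[lymph_rows] <- lab
  }
  cells$aggregate_id <- labels_all
  ids <- sort(unique(labels_all[!is.na(labels_all) & labels_all > 0]))
  aggs <- purrr::map_dfr(ids, function(k) {
    rows <- which(!is.na(labels_all) & labels_all == k)
    sub <- cells[rows, ]
    xy <- cbind(sub$x_um, sub$y_um)
    h <- grDevices::chull(xy)
    hull <- xy[h, , drop = FALSE]
    comp <- aggregate_composition(sub, config)
    tibble::tibble(aggregate_id = k, n_cells = length(rows),
                   area_mm2 = polygon_area_um2(hull) / 1e6,
                   centroid_x = mean(sub$x_um), centroid_y = mean(sub$y_um),
                   n_b = comp["b"], n_cd4 = comp["cd4"], n_cd8 = comp["cd8"],
                   n_tfh = comp["tfh"], n_bcl6 = comp["bcl6"],
                   hull = list(hull))
  })
  if (!nrow(aggs)) {
    aggs <- tibble::tibble(aggregate_id = integer(0), n_cells = integer(0),
                           area_mm2 = numeric(0), centroid_x = numeric(0),
                           centroid_y = numeric(0), n_b = numeric(0),
                           n_cd4 = numeric(0), n_cd8 = numeric(0),
                           n_tfh = numeric(0), n_bcl6 = numeric(0), hull = list())
  }
  aggs <- classify_maturity(aggs, rules)
  structure(list(aggregates = aggs, cells = cells,
                 params = list(eps_um = eps_um, min_cells = min_cells,
                               lymphocyte_subsets = lymphocyte_subsets,
                               rules = rules)),
            class = "la_set")
}

aggregate_composition <- function(sub, config) {
  memb <- membership_long(sub, config)
  cnt <- function(s) sum(memb$subset == s)
  bcl6 <- if ("BCL6" %in% names(sub)) sum(as.logical(sub$BCL6)) else cnt("tfh")
  c(b = cnt("b_cell"), cd4 = cnt("cd4_t"), cd8 = cnt("cd8_t"),
    tfh = cnt("tfh"), bcl6 = bcl6)
}

#' Maturity rules for lymphoid aggregates
#'
#' A detected aggregate is a mature tertiary lymphoid structure when it shows
#' germinal-center evidence (at least `min_gc_cells` BCL6+ members) inside a
#' B-cell follicle (B-cell fraction >= `min_b_fraction`); otherwise it remains
#' a plain lymphoid aggregate.
#'
#' @param min_gc_cells Minimum BCL6+ members for a germinal center.
#' @param min_b_fraction Minimum B-cell fraction of members.
#' @return A named list of rules.
#' @export
maturity_rules <- function(min_gc_cells = 10, min_b_fraction = 0.3) {
  if (min_gc_cells <= 0 && min_b_fraction <= 0) {
    rlang::warn("degenerate maturity rules: every aggregate will classify as mature_TLS")
  }
  list(min_gc_cells = min_gc_cells, min_b_fraction = min_b_fraction)
}

#' Classify aggregate maturity
#'
#' @param aggs Aggregate tibble (from an `la_set`) with `n_bcl6`, `n_b`,
#'   `n_cells`.
#' @param rules From [maturity_rules()].
#' @return `aggs` with a `maturity` factor (`LA` / `mature_TLS`).
#' @export
classify_maturity <- function(aggs, rules = maturity_rules()) {
  mature <- aggs$n_bcl6 >= rules$min_gc_cells &
    (aggs$n_b / pmax(aggs$n_cells, 1)) >= rules$min_b_fraction
  aggs$maturity <- factor(ifelse(mature, "mature_TLS", "LA"),
                          levels = c("LA", "mature_TLS"))
  aggs
}

#' Summarize aggregates per band and across a cohort
#'
#' Counts aggregates per band by centroid band, computes each band's aggregate
#' area fraction (percent of band area covered by aggregate hulls, by raster
#' intersection of hull polygons with the signed-distance bands), and flags
#' intratumoral presence (any aggregate whose centroid lies in the tumor core
#' or inner invasive margin).
#'
#' @param las An `la_set` from [detect_aggregates()].
#' @param map A `compartment_map` for the same sample.
#' @param sample_id Optional sample label.
#' @param intersection_resolution Raster resolution (um) for hull-band
#'   intersection areas.
#' @return List with `per_band` (tibble: band, `n_aggregates`, `n_mature`,
#'   `aggregate_area_mm2`, `area_fraction_pct`) and `intratumoral_presence`
#'   (logical).
#' @export
summarize_aggregates <- function(las, map, sample_id = NULL,
                                 intersection_resolution = 5) {
  aggs <- las$aggregates
  sid <- sample_id %||% "sample1"
  bands <- factor(band_levels(), levels = band_levels())
  if (nrow(aggs)) {
    cd <- signed_distance(cbind(aggs$centroid_x, aggs$centroid_y), map$geometry)
    aggs$centroid_band <- assign_band(cd, map$cutoffs, map$merge_buffer)
    split_areas <- purrr::map_dfr(seq_len(nrow(aggs)), function(i) {
      ar <- hull_band_areas(aggs$hull[[i]], map, intersection_resolution)
      ar$aggregate_id <- aggs$aggregate_id[i]
      ar
    })
  } else {
    aggs$centroid_band <- factor(character(0), levels = band_levels())
    split_areas <- tibble::tibble(band = bands[0], area_mm2 = numeric(0),
                                  aggregate_id = integer(0))
  }
  counts <- aggs |>
    dplyr::count(band = .data$centroid_band, name = "n_aggregates") |>
    tidyr::complete(band = bands, fill = list(n_aggregates = 0L))
  mature <- aggs |>
    dplyr::filter(.data$maturity == "mature_TLS") |>
    dplyr::count(band = .data$centroid_band, name = "n_mature") |>
    tidyr::complete(band = bands, fill = list(n_mature = 0L))
  areas <- split_areas |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(aggregate_area_mm2 = sum(.data$area_mm2), .groups = "drop") |>
    tidyr::complete(band = bands, fill = list(aggregate_area_mm2 = 0))
  per_band <- counts |>
    dplyr::left_join(mature, by = "band") |>
    dplyr::left_join(areas, by = "band") |>
    dplyr::left_join(map$areas, by = "band") |>
    dplyr::mutate(sample_id = sid,
                  area_fraction_pct = ifelse(.data$area_mm2 > 0,
                                             100 * .data$aggregate_area_mm2 / .data$area_mm2,
                                             NA_real_)) |>
    dplyr::select("sample_id", "band", "n_aggregates", "n_mature",
                  "aggregate_area_mm2", "area_fraction_pct")
  intratumoral <- any(aggs$centroid_band %in% c("core", "inner_margin"))
  list(per_band = per_band, intratumoral_presence = intratumoral,
       aggregates = aggs, split_areas = split_areas)
}

# Area (mm^2) of a hull polygon falling in each band, by rastering the hull
# bounding box and classifying pixel centres by exact signed distance.
hull_band_areas <- function(hull, map, resolution = 5) {
  bb <- apply(hull, 2, range)
  nx <- max(2L, ceiling((bb[2, 1] - bb[1, 1]) / resolution))
  ny <- max(2L, ceiling((bb[2, 2] - bb[1, 2]) / resolution))
  xc <- bb[1, 1] + (seq_len(nx) - 0.5) * resolution
  yc <- bb[1, 2] + (seq_len(ny) - 0.5) * resolution
  g <- expand.grid(x = xc, y = yc)
  inside <- point_in_polygon(g$x, g$y, hull)
  if (!any(inside)) {
    return(tibble::tibble(band = factor(character(0), levels = band_levels()),
                          area_mm2 = numeric(0)))
  }
  d <- signed_distance(cbind(g$x[inside], g$y[inside]), map$geometry)
  b <- assign_band(d, map$cutoffs, map$merge_buffer)
  tab <- table(b)
  tibble::tibble(band = factor(names(tab), levels = band_levels()),
                 area_mm2 = as.numeric(tab) * resolution^2 / 1e6) |>
    dplyr::filter(.data$area_mm2 > 0)
}

#' Densities of sporadic (non-aggregated) cells
#'
#' [density_table()] recomputed after removing aggregate members, i.e. the
#' background infiltrate once lymphoid aggregates are excluded.
#'
#' @inheritParams density_table
#' @param las An `la_set` whose `cells` carry `aggregate_id`.
#' @return A tidy density tibble.
#' @export
sporadic_densities <- function(las, map, config = default_gating_config(), ...) {
  cells <- las$cells
  keep <- is.na(cells$aggregate_id) | cells$aggregate_id == 0L
  density_table(cells[keep, ], map, config = config, ...)
}

#' @export
print.la_set <- function(x, ...) {
  cat(sprintf("<la_set> %d aggregate(s) (%d mature TLS) from %d cells; eps = %g um, min_cells = %d\n",
              nrow(x$aggregates), sum(x$aggregates$maturity == "mature_TLS"),
              nrow(x$cells), x$params$eps_um, x$params$min_cells))
  invisible(x)
}

#' Tidy an aggregate set
#'
#' One row per detected aggregate with size, area, centroid, composition and
#' maturity (hull geometry dropped).
#'
#' @param x An `la_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.la_set <- function(x, ...) {
  dplyr::select(x$aggregates, -"hull")
}

#' Glance at an aggregate set
#'
#' @param x An `la_set`.
#' @param ... Unused.
#' @return One-row tibble: aggregate count, mature count, total area, total
#'   member cells, sporadic lymphocyte count.
#' @export
glance.la_set <- function(x, ...) {
  tibble::tibble(n_aggregates = nrow(x$aggregates),
                 n_mature_tls = sum(x$aggregates$maturity == "mature_TLS"),
                 total_area_mm2 = sum(x$aggregates$area_mm2),
                 n_aggregated_cells = sum(x$aggregates$n_cells),
                 n_sporadic_lymphocytes = sum(x$cells$aggregate_id == 0L, na.rm = TRUE))
}
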