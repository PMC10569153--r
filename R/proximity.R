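#' Neighbor counts within a fixed radius
#'
#' For each source cell, the number of target cells whose centre-to-centre
#' distance is <= `r` (boundary inclusive). When source and target tables
#' share `cell_id`s, a cell is never its own neighbor. The default grid-bucket
#' index is exact and scales to whole-slide tables; `method = "brute"` is the
#' all-pairs reference path kept for verification.
#'
#' @param source,target Data frames with `x_um`, `y_um` and optionally
#'   `cell_id`.
#' @param r Radius in um (> 0).
#' @param method `"grid"` (default) or `"brute"`.
#' @return Integer vector of counts, one per source row (input order).
#' @export
neighbor_counts <- function(source, target, r, method = c("grid", "brute")) {
  method <- rlang::arg_match(method)
  stopifnot(r > 0)
  sxy <- points_xy(source); txy <- points_xy(target)
  sid <- if (!is.matrix(source) && "cell_id" %in% names(source)) source$cell_id else NULL
  tid <- if (!is.matrix(target) && "cell_id" %in% names(target)) target$cell_id else NULL
  ns <- nrow(sxy)
  if (!ns) return(integer(0))
  if (!nrow(txy)) return(integer(ns))
  if (method == "brute") {
    counts <- integer(ns)
    for (i in seq_len(ns)) {
      d2 <- (txy[, 1] - sxy[i, 1])^2 + (txy[, 2] - sxy[i, 2])^2
      hits <- d2 <= r^2
      if (!is.null(sid) && !is.null(tid)) hits <- hits & (tid != sid[i])
      counts[i] <- sum(hits)
    }
    return(counts)
  }
  pairs <- radius_pairs(sxy, txy, r)
  if (!is.null(sid) && !is.null(tid)) {
    pairs <- pairs[sid[pairs$si] != tid[pairs$ti], ]
  }
  counts <- tabulate(pairs$si, nbins = ns)
  as.integer(counts)
}

# All (source i, target j) index pairs with distance <= r, via grid buckets of
# side r joined over the 3x3 neighborhood. data.table keyed join keeps this
# near-linear for the radii used here.
radius_pairs <- function(sxy, txy, r) {
  x0 <- min(sxy[, 1], txy[, 1]); y0 <- min(sxy[, 2], txy[, 2])
  gsx <- as.integer(floor((sxy[, 1] - x0) / r)); gsy <- as.integer(floor((sxy[, 2] - y0) / r))
  gtx <- as.integer(floor((txy[, 1] - x0) / r)); gty <- as.integer(floor((txy[, 2] - y0) / r))
  tg <- data.table::data.table(gx = gtx, gy = gty, ti = seq_len(nrow(txy)),
                               tx = txy[, 1], ty = txy[, 2])
  data.table::setkey(tg, gx, gy)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  res <- vector("list", nrow(off))
  sg <- data.table::data.table(gx0 = gsx, gy0 = gsy, si = seq_len(nrow(sxy)),
                               sx = sxy[, 1], sy = sxy[, 2])
  for (k in seq_len(nrow(off))) {
    probe <- data.table::data.table(gx = sg$gx0 + off$dx[k], gy = sg$gy0 + off$dy[k],
                                    si = sg$si, sx = sg$sx, sy = sg$sy)
    hit <- tg[probe, on = c("gx", "gy"), nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hit)) {
      keep <- (hit$tx - hit$sx)^2 + (hit$ty - hit$sy)^2 <= r^2
      res[[k]] <- hit[keep, c("si", "ti")]
    }
  }
  out <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) {
    return(data.frame(si = integer(0), ti = integer(0)))
  }
  as.data.frame(out)
}

subset_cells <- function(cells, subset, config) {
  memb <- membership_long(cells, config)
  cells[sort(unique(memb$row[memb$subset == subset])), , drop = FALSE]
}

#' Mutual availability of two cell populations per band
#'
#' The direct-contact statistic: mean number of target cells within radius `r`
#' of each source cell, per histologic band, in both directions
#' (source -> target and target -> source). Band membership is taken from the
#' indexed (source) cell; neighbors may lie in any band, since contacts across
#' a band boundary are real contacts. Bands with no source cells are missing.
#'
#' @param cells Gated cell table (or `NULL` to use `map$cells`).
#' @param map A `compartment_map`.
#' @param source,target Subset names (hierarchical membership).
#' @param r Contact radius in um; 10 um is the direct-contact radius.
#' @param config Gating config.
#' @param sample_id Optional sample label.
#' @return Tibble with one row per band x direction: `source`, `target`,
#'   `mean_neighbors`, `n_source`, `n_target`.
#' @export
mutual_availability <- function(cells = NULL, map, source, target, r = 10,
                                config = default_gating_config(),
                                sample_id = NULL) {
  cells <- cells %||% map$cells
  assert_cols(cells, c("band", "x_um", "y_um"), "cells")
  sid <- sample_id %||% (if ("sample_id" %in% names(cells)) cells$sample_id[1] else "sample1")
  src <- subset_cells(cells, source, config)
  tgt <- subset_cells(cells, target, config)
  one_dir <- function(a, b, alab, blab) {
    cnt <- neighbor_counts(a, b, r)
    tibble::tibble(band = a$band, n = cnt) |>
      dplyr::group_by(.data$band) |>
      dplyr::summarise(mean_neighbors = mean(.data$n), n_source = dplyr::n(),
                       .groups = "drop") |>
      tidyr::complete(band = factor(band_levels(), levels = band_levels()),
                      fill = list(mean_neighbors = NA_real_, n_source = 0L)) |>
      dplyr::mutate(source = alab, target = blab, n_target = nrow(b))
  }
  dplyr::bind_rows(one_dir(src, tgt, source, target),
                   one_dir(tgt, src, target, source)) |>
    dplyr::mutate(sample_id = sid, radius_um = r) |>
    dplyr::select("sample_id", "band", "source", "target", "radius_um",
                  "mean_neighbors", "n_source", "n_target")
}

#' Contact fraction and nearest-neighbor distance
#'
#' Per band (of the source cell): the percentage of source cells with at least
#' one target within radius `r`, and the mean nearest-target distance over
#' source cells (targets anywhere in the sample, any band). Self-pairs are
#' excluded when the populations overlap.
#'
#' @inheritParams mutual_availability
#' @return Tibble with `contact_fraction` (percent), `mean_nn_um`,
#'   `n_source`, `n_target` per band.
#' @export
contact_stats <- function(cells = NULL, map, source, target, r = 10,
                          config = default_gating_config(), sample_id = NULL) {
  cells <- cells %||% map$cells
  assert_cols(cells, c("band", "x_um", "y_um"), "cells")
  sid <- sample_id %||% (if ("sample_id" %in% names(cells)) cells$sample_id[1] else "sample1")
  src <- subset_cells(cells, source, config)
  tgt <- subset_cells(cells, target, config)
  nn <- nearest_target_distance(src, tgt)
  cnt <- if (nrow(tgt)) neighbor_counts(src, tgt, r) else integer(nrow(src))
  tibble::tibble(band = src$band, contact = cnt > 0, nn = nn) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(contact_fraction = 100 * mean(.data$contact),
                     mean_nn_um = mean(.data$nn[is.finite(.data$nn)]),
                     n_source = dplyr::n(), .groups = "drop") |>
    tidyr::complete(band = factor(band_levels(), levels = band_levels()),
                    fill = list(contact_fraction = NA_real_, mean_nn_um = NA_real_,
                                n_source = 0L)) |>
    dplyr::mutate(sample_id = sid, source = source, target = target,
                  radius_um = r, n_target = nrow(tgt),
                  mean_nn_um = ifelse(is.nan(.data$mean_nn_um), NA_real_, .data$mean_nn_um)) |>
    dplyr::select("sample_id", "band", "source", "target", "radius_um",
                  "contact_fraction", "mean_nn_um", "n_source", "n_target")
}

# Exact nearest-neighbor distance from each source to the target set,
# excluding identical cell_ids. Expanding-radius grid search with brute-force
# fallback for the remainder.
nearest_target_distance <- function(src, tgt) {
  if (!nrow(src)) return(numeric(0))
  if (!nrow(tgt)) return(rep(Inf, nrow(src)))
  sxy <- points_xy(src); txy <- points_xy(tgt)
  sid <- if ("cell_id" %in% names(src)) src$cell_id else NULL
  tid <- if ("cell_id" %in% names(tgt)) tgt$cell_id else NULL
  nn <- rep(Inf, nrow(sxy))
  pending <- seq_len(nrow(sxy))
  span <- max(diff(range(sxy[, 1], txy[, 1])), diff(range(sxy[, 2], txy[, 2])), 1)
  r <- max(span / 64, 1)
  while (length(pending) && r <= 2 * span) {
    pr <- radius_pairs(sxy[pending, , drop = FALSE], txy, r)
    if (nrow(pr)) {
      if (!is.null(sid) && !is.null(tid)) {
        pr <- pr[sid[pending[pr$si]] != tid[pr$ti], ]
      }
      if (nrow(pr)) {
        d <- sqrt((sxy[pending[pr$si], 1] - txy[pr$ti, 1])^2 +
                  (sxy[pending[pr$si], 2] - txy[pr$ti, 2])^2)
        agg <- tapply(d, pr$si, min)
        idx <- pending[as.integer(names(agg))]
        nn[idx] <- pmin(nn[idx], as.numeric(agg))
      }
    }
    pending <- pending[!is.finite(nn[pending])]
    r <- r * 2
  }
  if (length(pending)) {  # degenerate fallback (e.g. all targets are self)
    for (i in pending) {
      d2 <- (txy[, 1] - sxy[i, 1])^2 + (txy[, 2] - sxy[i, 2])^2
      if (!is.null(sid) && !is.null(tid)) d2[tid == sid[i]] <- Inf
      nn[i] <- sqrt(min(d2))
    }
  }
  nn
}
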