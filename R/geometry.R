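#' Tissue geometry: tumor boundary, necrosis, extent
#'
#' Container for the vector geometry of one tissue section: one or more simple
#' tumor-boundary polygons, optional necrosis polygons (inside the tumor), and
#' the rectangular tissue extent. All coordinates are micrometres, Cartesian,
#' with y increasing downward (image convention).
#'
#' @param tumor A two-column matrix of polygon vertices (x, y in um), or a list
#'   of such matrices for multiple tumor islands. Polygons must be simple
#'   (non-self-intersecting); they are closed implicitly.
#' @param extent Numeric length-4 vector `c(xmin, xmax, ymin, ymax)` in um.
#' @param necrosis Optional list of necrosis polygons (matrices), expected
#'   inside the tumor.
#' @return An object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(tumor, extent, necrosis = list()) {
  if (is.matrix(tumor)) tumor <- list(tumor)
  tumor <- lapply(tumor, as_polygon)
  necrosis <- lapply(necrosis, as_polygon)
  extent <- as.numeric(extent)
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4]) {
    rlang::abort("extent must be c(xmin, xmax, ymin, ymax) with min < max")
  }
  for (p in tumor) {
    if (!polygon_is_simple(p)) {
      rlang::abort("tumor polygon is self-intersecting; a simple polygon is required")
    }
    bb <- apply(p, 2, range)
    if (bb[1, 1] < extent[1] || bb[2, 1] > extent[2] ||
        bb[1, 2] < extent[3] || bb[2, 2] > extent[4]) {
      rlang::abort("tumor polygon extends beyond the tissue extent")
    }
  }
  structure(list(tumor = tumor, necrosis = necrosis, extent = extent),
            class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("<tissue_geometry> %d tumor island(s), %d necrosis polygon(s)\n",
              length(x$tumor), length(x$necrosis)))
  cat(sprintf("  extent: [%g, %g] x [%g, %g] um (%.1f x %.1f mm)\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              diff(x$extent[1:2]) / 1000, diff(x$extent[3:4]) / 1000))
  invisible(x)
}

as_polygon <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2 || nrow(p) < 3) rlang::abort("a polygon needs >= 3 (x, y) vertices")
  # drop an explicitly repeated closing vertex
  n <- nrow(p)
  if (all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3) rlang::abort("a polygon needs >= 3 distinct vertices")
  unname(p)
}

# Shoelace area (um^2), absolute value.
polygon_area_um2 <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
  abs(sum(x * yj - xj * y)) / 2
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
  cr <- x * yj - xj * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(p))
  c(sum((x + xj) * cr), sum((y + yj) * cr)) / (6 * a)
}

# O(n^2) segment-intersection test; adequate for digitised boundaries.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]  # skip edges sharing a vertex with edge 1
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE], b[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(p2 - p1, t(t(q1) - p1))
  d2 <- cross2(p2 - p1, t(t(q2) - p1))
  d3 <- cross2v(q2 - q1, p1, q1)
  d4 <- cross2v(q2 - q1, p2, q1)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

cross2 <- function(v, w) v[1] * w[, 2] - v[2] * w[, 1]
cross2v <- function(v, pt, o) v[, 1] * (pt[2] - o[, 2]) - v[, 2] * (pt[1] - o[, 1])

# Vectorised ray-casting point-in-polygon (even-odd rule).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  for (e in seq_len(n)) {
    x1 <- xs[j[e]]; y1 <- ys[j[e]]; x2 <- xs[e]; y2 <- ys[e]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

point_in_any <- function(px, py, polys) {
  inside <- rep(FALSE, length(px))
  for (p in polys) inside <- inside | point_in_polygon(px, py, p)
  inside
}

# Min Euclidean distance from points to a polygon boundary (vectorised over points).
dist_to_boundary <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  nx <- c(xs[-1], xs[1]); ny <- c(ys[-1], ys[1])
  dmin <- rep(Inf, length(px))
  for (e in seq_len(n)) {
    ex <- nx[e] - xs[e]; ey <- ny[e] - ys[e]
    len2 <- ex * ex + ey * ey
    if (len2 == 0) {
      d2 <- (px - xs[e])^2 + (py - ys[e])^2
    } else {
      t <- pmin(1, pmax(0, ((px - xs[e]) * ex + (py - ys[e]) * ey) / len2))
      d2 <- (px - xs[e] - t * ex)^2 + (py - ys[e] - t * ey)^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Signed distance to the tumor boundary
#'
#' Signed Euclidean distance from points to the nearest tumor-boundary point:
#' negative strictly inside the tumor (any island), positive outside, zero on
#' the boundary. This is the distance underlying all band definitions.
#'
#' @param points A data frame with `x_um`, `y_um` columns, or a two-column
#'   matrix of coordinates in um.
#' @param geometry A [tissue_geometry()].
#' @param method `"exact"` computes point-to-segment distances against the
#'   polygon(s); `"raster"` looks points up in a Euclidean distance-transform
#'   field (see [distance_field()]), the whole-slide-scale path.
#' @param resolution Raster resolution in um/pixel (raster method).
#' @param field Optional precomputed [distance_field()] to reuse.
#' @return Numeric vector of signed distances (um).
#' @export
signed_distance <- function(points, geometry, method = c("exact", "raster"),
                            resolution = 10, field = NULL) {
  method <- rlang::arg_match(method)
  xy <- points_xy(points)
  if (!nrow(xy)) return(numeric(0))
  if (method == "exact") {
    d <- rep(Inf, nrow(xy))
    for (p in geometry$tumor) d <- pmin(d, dist_to_boundary(xy[, 1], xy[, 2], p))
    inside <- point_in_any(xy[, 1], xy[, 2], geometry$tumor)
    ifelse(inside, -d, d)
  } else {
    fld <- field %||% distance_field(geometry, resolution)
    lookup_field(fld, xy[, 1], xy[, 2])
  }
}

points_xy <- function(points) {
  if (is.matrix(points)) {
    xy <- points
  } else {
    assert_cols(points, c("x_um", "y_um"), "points")
    xy <- cbind(points$x_um, points$y_um)
  }
  storage.mode(xy) <- "double"
  xy
}

#' Raster signed-distance field
#'
#' Rasterizes the tumor mask over the tissue extent and computes the signed
#' Euclidean distance transform (um) at pixel centres, negative inside the
#' tumor. Used for band areas, simulation intensity lookups, and fast per-cell
#' distances on large inputs.
#'
#' @inheritParams signed_distance
#' @param resolution Pixel size in um.
#' @return A list with the distance matrix `d` (indexed `[ix, iy]`), pixel
#'   centre coordinate vectors `xc`, `yc`, `resolution`, and the tumor `mask`.
#' @export
distance_field <- function(geometry, resolution = 10) {
  ext <- geometry$extent
  nx <- max(2L, ceiling((ext[2] - ext[1]) / resolution))
  ny <- max(2L, ceiling((ext[4] - ext[3]) / resolution))
  xc <- ext[1] + (seq_len(nx) - 0.5) * resolution
  yc <- ext[3] + (seq_len(ny) - 0.5) * resolution
  mask <- matrix(FALSE, nx, ny)
  for (p in geometry$tumor) mask <- mask | rasterize_polygon(p, xc, yc)
  m <- matrix(as.numeric(mask), nx, ny)
  din <- EBImage::distmap(m)          # distance (px) of tumor pixels to outside
  dout <- EBImage::distmap(1 - m)     # distance (px) of outside pixels to tumor
  d <- (as.matrix(dout) - as.matrix(din)) * resolution
  list(d = d, xc = xc, yc = yc, resolution = resolution, mask = mask,
       extent = ext)
}

# Scanline polygon rasterization at pixel centres. Returns nx x ny logical.
rasterize_polygon <- function(poly, xc, yc) {
  nx <- length(xc); ny <- length(yc)
  mask <- matrix(FALSE, nx, ny)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  rows <- integer(0); xint <- numeric(0)
  for (e in seq_len(n)) {
    y1 <- ys[j[e]]; y2 <- ys[e]
    if (y1 == y2) next
    x1 <- xs[j[e]]; x2 <- xs[e]
    lo <- min(y1, y2); hi <- max(y1, y2)
    iy <- which(yc >= lo & yc < hi)   # half-open: vertices counted once
    if (!length(iy)) next
    rows <- c(rows, iy)
    xint <- c(xint, x1 + (yc[iy] - y1) / (y2 - y1) * (x2 - x1))
  }
  if (!length(rows)) return(mask)
  ord <- order(rows, xint)
  rows <- rows[ord]; xint <- xint[ord]
  starts <- which(!duplicated(rows))
  ends <- c(starts[-1] - 1L, length(rows))
  x0 <- xc[1]; res <- xc[2] - xc[1]
  for (k in seq_along(starts)) {
    xi <- xint[starts[k]:ends[k]]
    m <- length(xi) %/% 2 * 2
    if (!m) next
    for (p in seq(1, m, by = 2)) {
      i1 <- ceiling((xi[p] - x0) / res + 0.5)
      i2 <- floor((xi[p + 1] - x0) / res + 0.5)
      i1 <- max(1L, i1); i2 <- min(nx, i2)
      if (i1 <= i2) mask[i1:i2, rows[starts[k]]] <- TRUE
    }
  }
  mask
}

# Nearest-pixel lookup in a distance field.
lookup_field <- function(field, px, py) {
  res <- field$resolution
  ix <- pmin(length(field$xc), pmax(1L, as.integer(round((px - field$extent[1]) / res + 0.5))))
  iy <- pmin(length(field$yc), pmax(1L, as.integer(round((py - field$extent[3]) / res + 0.5))))
  field$d[cbind(ix, iy)]
}
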