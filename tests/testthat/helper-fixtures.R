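# shared fixture builders; everything is generated in code

circle_polygon <- function(radius = 2000, center = c(7000, 7000), n = 256) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(theta), center[2] + radius * sin(theta))
}

circle_geometry <- function(radius = 2000, extent = 14000, n = 256, ...) {
  tissue_geometry(circle_polygon(radius, c(extent / 2, extent / 2), n),
                  c(0, extent, 0, extent), ...)
}

# a constant-intensity single-subset archetype for Poisson checks
flat_archetype <- function(lambda = 100, subset = "cd8_t", extra = NULL) {
  pr <- tibble::tibble(subset = subset, base_in = lambda, base_out = lambda,
                       mid = 0, slope = 30, bump = 0, bump_center = 0,
                       bump_sd = 100)
  if (!is.null(extra)) pr <- dplyr::bind_rows(pr, extra)
  archetype_spec("flat", pr)
}

# cells laid out on a regular grid inside a box
grid_cells <- function(n_side = 10, spacing = 50, origin = c(100, 100),
                       subset = "cd8_t") {
  g <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
  tibble::tibble(cell_id = sprintf("g%04d", seq_len(nrow(g))),
                 x_um = origin[1] + (g$ix - 1) * spacing,
                 y_um = origin[2] + (g$iy - 1) * spacing,
                 truth_subset = subset)
}

# boolean marker columns for a table of truth_subset labels, no randomness
truth_markers_deterministic <- function(cells) {
  lm <- list(tumor = "CK20", treg = c("CD3", "CD4", "FOXP3"),
             tfh = c("CD3", "CD4", "BCL6"),
             cd4_activated = c("CD3", "CD4", "HLADR"),
             cd4_tcf1 = c("CD3", "CD4", "TCF1"),
             cd8_activated = c("CD3", "CD8", "HLADR"),
             cd8_stem = c("CD3", "CD8", "TCF1"),
             cd4_t = c("CD3", "CD4"), cd8_t = c("CD3", "CD8"),
             gd_t = c("CD3", "TCRd"), b_cell = "CD20", m1_tam = "CD68",
             m2_tam = c("CD68", "CD163"), tan = "CD66b", apc = "HLADR",
             other = character(0))
  mk <- unique(c(unlist(lm), "PD1", "PDL1"))
  for (m in mk) cells[[m]] <- FALSE
  for (leaf in names(lm)) {
    rows <- cells$truth_subset == leaf
    for (m in lm[[leaf]]) cells[[m]][rows] <- TRUE
  }
  cells
}

# cells at given coordinates with one subset, markers set
cells_at <- function(x, y, subset = "cd8_t", id_prefix = "c") {
  truth_markers_deterministic(
    tibble::tibble(cell_id = sprintf("%s%04d", id_prefix, seq_along(x)),
                   x_um = x, y_um = y, truth_subset = subset))
}
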