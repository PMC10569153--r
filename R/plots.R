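#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

geom_polygon_path <- function(poly, ...) {
  df <- data.frame(x = c(poly[, 1], poly[1, 1]), y = c(poly[, 2], poly[1, 2]))
  ggplot2::geom_path(data = df, ggplot2::aes(x = .data$x, y = .data$y), ...)
}

#' Plot a synthetic tissue
#'
#' Cell positions coloured by ground-truth subset with the tumor boundary and
#' planted aggregate hulls overlaid. y is reversed (image convention).
#'
#' @param object A `synthetic_tissue`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synthetic_tissue <- function(object, ...) {
  p <- ggplot2::ggplot(object$cells,
                       ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    colour = .data$truth_subset)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6)
  for (poly in object$geometry$tumor) p <- p + geom_polygon_path(poly, colour = "black")
  for (i in seq_len(nrow(object$truth$aggregates))) {
    p <- p + geom_polygon_path(object$truth$aggregates$polygon[[i]],
                               colour = "red", linetype = 2)
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "subset") +
    ggplot2::theme_minimal()
}

#' Plot a compartment map
#'
#' Cells coloured by histologic band with the tumor boundary overlaid.
#'
#' @param object A `compartment_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.compartment_map <- function(object, ...) {
  p <- ggplot2::ggplot(object$cells,
                       ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    colour = .data$band)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6)
  for (poly in object$geometry$tumor) p <- p + geom_polygon_path(poly, colour = "black")
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "band") +
    ggplot2::theme_minimal()
}

#' Plot detected lymphoid aggregates
#'
#' Lymphocytes (grey: sporadic; coloured: aggregated) with detected hulls.
#'
#' @param object An `la_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.la_set <- function(object, ...) {
  cells <- dplyr::filter(object$cells, !is.na(.data$aggregate_id))
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    colour = factor(.data$aggregate_id))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7)
  for (i in seq_len(nrow(object$aggregates))) {
    p <- p + geom_polygon_path(object$aggregates$hull[[i]], colour = "black")
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "aggregate") +
    ggplot2::theme_minimal()
}

#' Density profile plot
#'
#' Log-density per band and subset, across the samples of a cohort density
#' table (boxplots when several samples are present).
#'
#' @param density A density tibble from [density_table()].
#' @param subsets Optional subset filter.
#' @return A ggplot.
#' @export
plot_density <- function(density, subsets = NULL) {
  d <- density
  if (!is.null(subsets)) d <- dplyr::filter(d, .data$subset %in% subsets)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band, y = .data$log_density)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~subset, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log10(cells/mm^2 + 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Correlation heat map
#'
#' Tile plot of a tidy correlation table (e.g. [region_pair_pcc()] output).
#'
#' @param pcc Tibble with `subset` and `pcc` columns (and `organ` facets when
#'   present).
#' @return A ggplot.
#' @export
plot_correlation <- function(pcc) {
  p <- ggplot2::ggplot(pcc, ggplot2::aes(x = 1, y = .data$subset, fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if ("organ" %in% names(pcc)) p <- p + ggplot2::facet_wrap(~organ)
  p
}
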