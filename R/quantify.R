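# Long-format subset membership for counting. Uses marker-based gates when the
# marker columns are present; otherwise falls back to terminal labels expanded
# through the gate hierarchy (a `treg` label also counts as `cd4_t`).
membership_long <- function(cells, config = default_gating_config()) {
  cache <- attr(cells, "mif_membership", exact = TRUE)
  if (!is.null(cache) && identical(cache$key, rlang::hash(config)) &&
      identical(cache$n, nrow(cells))) {
    return(cache$memb)
  }
  have_markers <- all(setdiff(gating_markers(config), c("PD1", "PDL1")) %in% names(cells))
  if (have_markers) {
    m <- subset_membership(cells, config)
    idx <- which(m, arr.ind = TRUE)
    out <- tibble::tibble(row = idx[, 1], subset = colnames(m)[idx[, 2]])
  } else {
    assert_cols(cells, "subset", "cells")
    lab <- as.character(cells$subset)
    anc <- stats::setNames(config$parent, config$name)
    expand <- lapply(stats::setNames(config$name, config$name), function(s) {
      chain <- s
      while (!is.na(anc[[chain[length(chain)]]] %||% NA)) chain <- c(chain, anc[[chain[length(chain)]]])
      chain
    })
    hits <- expand[lab]
    out <- tibble::tibble(row = rep(seq_along(lab), lengths(hits)),
                          subset = unlist(hits, use.names = FALSE))
    out <- out[!is.na(out$subset), ]
  }
  out
}

# Attach a membership cache so repeated quantification passes over the same
# table reuse one gating evaluation. Subsetting the table drops the cache.
cache_membership <- function(cells, config = default_gating_config()) {
  memb <- membership_long(cells, config)
  attr(cells, "mif_membership") <- list(key = rlang::hash(config),
                                        n = nrow(cells), memb = memb)
  cells
}

#' Per-band, per-subset cell densities
#'
#' One row per sample x band x subset with raw count, band area (mm^2),
#' density (cells/mm^2) and log-density `log10(density + pseudocount)`.
#' Subset counting is hierarchical: a Treg contributes to both the `treg` and
#' `cd4_t` rows. Bands with zero area yield rows with missing density; the
#' buffer zone is dropped unless `include_buffer = TRUE`.
#'
#' @param cells Gated cell table (or `NULL` to use `map$cells`).
#' @param map A `compartment_map` from [compartmentalize()].
#' @param config Gating config defining the subsets counted.
#' @param subsets Subsets to report (default: the 14 immune subsets plus
#'   `tumor`).
#' @param pseudocount Added to density before log10 (cells/mm^2).
#' @param include_buffer Keep the 2-5 mm buffer zone rows.
#' @param sample_id Sample identifier recycled over rows; taken from a
#'   `sample_id` column when present.
#' @return A tidy tibble (`DensityTable`).
#' @export
density_table <- function(cells = NULL, map, config = default_gating_config(),
                          subsets = NULL, pseudocount = 1,
                          include_buffer = FALSE, sample_id = NULL) {
  cells <- cells %||% map$cells
  assert_cols(cells, "band", "cells")
  subsets <- subsets %||% c(immune_subsets(config), "tumor")
  sid <- sample_id %||% (if ("sample_id" %in% names(cells)) cells$sample_id[1] else "sample1")
  memb <- membership_long(cells, config)
  memb$band <- cells$band[memb$row]
  counts <- memb |>
    dplyr::filter(.data$subset %in% subsets) |>
    dplyr::count(.data$band, .data$subset, name = "count") |>
    tidyr::complete(band = factor(band_levels(), levels = band_levels()),
                    subset = subsets, fill = list(count = 0L))
  out <- counts |>
    dplyr::left_join(map$areas, by = "band") |>
    dplyr::mutate(sample_id = sid,
                  area_mm2 = tidyr::replace_na(.data$area_mm2, 0),
                  density = ifelse(.data$area_mm2 > 0, .data$count / .data$area_mm2, NA_real_),
                  log_density = log10(.data$density + pseudocount)) |>
    dplyr::select("sample_id", "band", "subset", "count", "area_mm2",
                  "density", "log_density")
  if (!include_buffer) out <- dplyr::filter(out, .data$band != "buffer")
  dplyr::arrange(out, .data$band, .data$subset)
}

#' Fractions of one subset within another, per band
#'
#' Percentage of denominator-subset cells that also belong to the numerator
#' (e.g. FOXP3+ Tregs within CD4 T cells; PD-1+ cells within a lymphocyte
#' subset via `flag`). Numerator membership must be nested within the
#' denominator; bands with an empty denominator are reported as missing,
#' never as zero.
#'
#' @inheritParams density_table
#' @param numerator,denominator Subset names from the gating config. The
#'   numerator may also be a denominator subset combined with `flag`.
#' @param flag Optional functional flag column (`"pd1"` or `"pdl1"`); when
#'   given, the numerator is denominator-members with the flag set.
#' @return Tibble with `sample_id`, `band`, `numerator`, `denominator`,
#'   `n_num`, `n_den`, `percentage`.
#' @export
fraction_table <- function(cells = NULL, map, numerator = NULL, denominator,
                           flag = NULL, config = default_gating_config(),
                           include_buffer = FALSE, sample_id = NULL) {
  cells <- cells %||% map$cells
  assert_cols(cells, "band", "cells")
  sid <- sample_id %||% (if ("sample_id" %in% names(cells)) cells$sample_id[1] else "sample1")
  memb <- membership_long(cells, config)
  den_rows <- memb$row[memb$subset == denominator]
  if (is.null(flag)) {
    if (is.null(numerator)) rlang::abort("supply a numerator subset or a flag")
    num_rows <- memb$row[memb$subset == numerator]
    if (!all(num_rows %in% den_rows)) {
      rlang::abort(sprintf("numerator '%s' is not nested within denominator '%s'",
                           numerator, denominator))
    }
    num_label <- numerator
  } else {
    assert_cols(cells, flag, "cells")
    num_rows <- intersect(den_rows, which(as.logical(cells[[flag]])))
    num_label <- paste0(flag, "+ ", numerator %||% denominator)
  }
  bands <- factor(band_levels(), levels = band_levels())
  out <- tibble::tibble(band = cells$band[den_rows],
                        is_num = den_rows %in% num_rows) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(n_num = sum(.data$is_num), n_den = dplyr::n(), .groups = "drop") |>
    tidyr::complete(band = bands, fill = list(n_num = 0L, n_den = 0L)) |>
    dplyr::mutate(sample_id = sid, numerator = num_label, denominator = denominator,
                  percentage = ifelse(.data$n_den > 0, 100 * .data$n_num / .data$n_den,
                                      NA_real_)) |>
    dplyr::select("sample_id", "band", "numerator", "denominator",
                  "n_num", "n_den", "percentage")
  if (!include_buffer) out <- dplyr::filter(out, .data$band != "buffer")
  out
}

#' Densities by intratumoral tissue subregion
#'
#' As [density_table()] but keyed by cancer island / stroma / necrosis within
#' the tumor core + inner invasive margin, using the subregion areas from
#' [classify_subregion()].
#'
#' @inheritParams density_table
#' @return Tidy tibble keyed by `subregion`.
#' @export
subregion_density <- function(cells = NULL, map, config = default_gating_config(),
                              subsets = NULL, pseudocount = 1, sample_id = NULL) {
  cells <- cells %||% map$cells
  assert_cols(cells, c("band", "subregion"), "cells")
  if (is.null(map$subregion_areas)) {
    rlang::abort("map has no subregion areas; run classify_subregion() first")
  }
  subsets <- subsets %||% c(immune_subsets(config), "tumor")
  sid <- sample_id %||% (if ("sample_id" %in% names(cells)) cells$sample_id[1] else "sample1")
  memb <- membership_long(cells, config)
  memb$subregion <- cells$subregion[memb$row]
  memb |>
    dplyr::filter(!is.na(.data$subregion), .data$subset %in% subsets) |>
    dplyr::count(.data$subregion, .data$subset, name = "count") |>
    tidyr::complete(subregion = factor(subregion_levels(), levels = subregion_levels()),
                    subset = subsets, fill = list(count = 0L)) |>
    dplyr::left_join(map$subregion_areas, by = "subregion") |>
    dplyr::mutate(sample_id = sid,
                  density = ifelse(.data$area_mm2 > 0, .data$count / .data$area_mm2, NA_real_),
                  log_density = log10(.data$density + pseudocount)) |>
    dplyr::select("sample_id", "subregion", "subset", "count", "area_mm2",
                  "density", "log_density") |>
    dplyr::arrange(.data$subregion, .data$subset)
}
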