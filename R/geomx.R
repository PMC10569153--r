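#' Normalize ROI protein counts to technical controls and area
#'
#' Divides each ROI's counts by its positive technical-control scale factor
#' (hybridization controls) and rescales to a reference area, yielding counts
#' per `ref_area_um2` of tissue.
#'
#' @param counts Tidy ROI x target table: columns `roi_id`, `target`, `count`,
#'   `area_um2`, `control_factor`, logical `is_isotype`, plus any metadata
#'   (`region`, `organ`).
#' @param ref_area_um2 Reference area (default 1e4 um^2).
#' @return The table with a `norm_count` column.
#' @export
normalize_counts <- function(counts, ref_area_um2 = 1e4) {
  assert_cols(counts, c("roi_id", "target", "count", "area_um2",
                        "control_factor", "is_isotype"), "counts")
  if (any(counts$control_factor <= 0)) {
    rlang::abort("technical-control factors must be positive")
  }
  if (any(counts$area_um2 <= 0)) rlang::abort("ROI areas must be positive")
  if (any(counts$count < 0)) rlang::abort("counts must be non-negative")
  dplyr::mutate(tibble::as_tibble(counts),
                norm_count = .data$count / .data$control_factor *
                  ref_area_um2 / .data$area_um2)
}

#' Signal-to-noise ratios against isotype controls
#'
#' SNR(ROI, target) = normalized count / geometric mean of that ROI's
#' normalized isotype-control counts. Zero isotype counts are floored at
#' `isotype_floor` (with a warning) so the geometric mean stays defined.
#'
#' @param normalized Output of [normalize_counts()].
#' @param isotype_floor Minimum isotype value used in the geometric mean.
#' @return Tibble of non-isotype rows with an `snr` column.
#' @export
compute_snr <- function(normalized, isotype_floor = 0.01) {
  assert_cols(normalized, c("roi_id", "target", "norm_count", "is_isotype"),
              "normalized")
  iso <- dplyr::filter(normalized, .data$is_isotype)
  if (!nrow(iso)) rlang::abort("no isotype-control rows present")
  if (any(iso$norm_count <= 0)) {
    rlang::warn(sprintf("isotype counts <= 0 floored at %g for the geometric mean",
                        isotype_floor))
  }
  geo <- iso |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(iso_geomean = exp(mean(log(pmax(.data$norm_count, isotype_floor)))),
                     .groups = "drop")
  missing_iso <- setdiff(unique(normalized$roi_id), geo$roi_id)
  if (length(missing_iso)) {
    rlang::abort(paste0("ROI(s) without isotype controls: ",
                        paste(missing_iso, collapse = ", ")))
  }
  normalized |>
    dplyr::filter(!.data$is_isotype) |>
    dplyr::left_join(geo, by = "roi_id") |>
    dplyr::mutate(snr = .data$norm_count / .data$iso_geomean)
}

#' Remove low signal-to-noise targets
#'
#' A target is removed when its summary SNR is strictly below `threshold`
#' (SNR exactly at the threshold is retained). The summary is the mean SNR
#' across ROIs by default; `per_roi = TRUE` instead masks individual
#' ROI x target values below the threshold.
#'
#' @param snr Output of [compute_snr()].
#' @param threshold SNR cutoff (default 2).
#' @param per_roi Mask per ROI instead of removing targets globally.
#' @return Filtered tibble; removed targets recorded in the
#'   `attr(, "removed")` tibble (`target`, `summary_snr`).
#' @export
filter_targets <- function(snr, threshold = 2, per_roi = FALSE) {
  assert_cols(snr, c("roi_id", "target", "snr"), "snr")
  if (per_roi) {
    out <- dplyr::filter(snr, .data$snr >= threshold)
    attr(out, "removed") <- dplyr::anti_join(
      snr, out, by = c("roi_id", "target"))[, c("roi_id", "target", "snr")]
    return(out)
  }
  summ <- snr |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(summary_snr = mean(.data$snr), .groups = "drop")
  removed <- dplyr::filter(summ, .data$summary_snr < threshold)
  out <- dplyr::filter(snr, !(.data$target %in% removed$target))
  attr(out, "removed") <- removed
  attr(out, "threshold") <- threshold
  out
}

#' Per-target marker comparisons between groups of ROIs
#'
#' For each retained target (and each region when present), a two-group
#' rank test on normalized counts between organ sites, BH-adjusted across
#' targets within the region family. Targets that were removed by the SNR
#' filter are reported with status `"filtered"`, never silently absent.
#'
#' @param filtered Output of [filter_targets()] (global mode).
#' @param group_a,group_b Organ labels to compare (from the `organ` column).
#' @param targets Optional target subset to report (defaults to all targets
#'   present before filtering, if recorded, else retained targets).
#' @param paired Passed to the rank test (signed-rank when `TRUE`).
#' @return Tidy tibble: `target`, `region`, `p`, `q`, `status`.
#' @export
compare_markers <- function(filtered, group_a, group_b, targets = NULL,
                            paired = FALSE) {
  assert_cols(filtered, c("target", "organ", "norm_count"), "filtered")
  removed <- attr(filtered, "removed")
  targets <- targets %||% unique(c(filtered$target,
                                   if (!is.null(removed)) removed$target))
  has_region <- "region" %in% names(filtered)
  dat <- dplyr::mutate(filtered,
                       region = if (has_region) .data$region else "all")
  res <- dat |>
    dplyr::filter(.data$organ %in% c(group_a, group_b)) |>
    dplyr::group_by(.data$region, .data$target) |>
    dplyr::summarise(p = rank_p(.data$norm_count, .data$organ, group_a, group_b,
                                paired = paired),
                     .groups = "drop_last") |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH"),
                  status = "tested") |>
    dplyr::ungroup()
  filt <- setdiff(targets, unique(res$target))
  if (length(filt)) {
    res <- dplyr::bind_rows(res, tibble::tibble(
      region = NA_character_, target = filt, p = NA_real_, q = NA_real_,
      status = "filtered"))
  }
  res
}

rank_p <- function(values, organ, a, b, paired = FALSE) {
  x <- values[organ == a]; y <- values[organ == b]
  if (!length(x) || !length(y)) return(NA_real_)
  suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                      exact = FALSE, correct = FALSE)$p.value)
}

#' Simulate a GeoMx-style ROI count table
#'
#' Generates ROI x target protein counts with isotype controls, per-ROI
#' technical-control factors and areas, organ/region structure, and optional
#' planted effects: noise targets whose signal sits at isotype level (removed
#' by SNR filtering) and fold-changes of named targets in chosen organ or
#' region groups.
#'
#' @param n_roi_per_group ROIs per organ x region group.
#' @param organs,regions Group label sets.
#' @param targets Target names (signal targets).
#' @param n_noise_targets Number of isotype-level noise targets appended.
#' @param n_isotypes Number of isotype controls.
#' @param base_signal Mean signal count scale for true targets.
#' @param iso_level Mean isotype/background count scale.
#' @param fold_changes Optional tibble `target`, `organ` (or NA), `region`
#'   (or NA), `fold` applied multiplicatively.
#' @param seed Integer seed.
#' @return Tidy count table ready for [normalize_counts()].
#' @export
simulate_roi_counts <- function(n_roi_per_group = 5,
                                organs = c("liver", "lung"),
                                regions = c("cancer_island", "stroma", "outer_margin"),
                                targets = paste0("T", sprintf("%02d", 1:20)),
                                n_noise_targets = 5, n_isotypes = 3,
                                base_signal = 80, iso_level = 8,
                                fold_changes = NULL, seed = 1) {
  with_seed(seed, {
    grid <- expand.grid(organ = organs, region = regions,
                        rep = seq_len(n_roi_per_group),
                        stringsAsFactors = FALSE)
    grid$roi_id <- sprintf("roi%03d", seq_len(nrow(grid)))
    grid$area_um2 <- stats::runif(nrow(grid), 4e4, 1.6e5)
    grid$control_factor <- stats::rlnorm(nrow(grid), 0, 0.15)
    noise <- if (n_noise_targets > 0) paste0("NOISE", seq_len(n_noise_targets)) else character(0)
    isos <- paste0("IgG", seq_len(n_isotypes))
    all_targets <- c(targets, noise, isos)
    base <- stats::setNames(c(stats::rlnorm(length(targets), log(base_signal), 0.4),
                              rep(iso_level, length(noise)),
                              rep(iso_level, length(isos))), all_targets)
    out <- tidyr::expand_grid(grid, target = all_targets) |>
      tibble::as_tibble()
    mu <- base[out$target]
    if (!is.null(fold_changes)) {
      for (i in seq_len(nrow(fold_changes))) {
        fc <- fold_changes[i, ]
        hit <- out$target == fc$target &
          (is.na(fc$organ) | out$organ == fc$organ) &
          (is.na(fc$region) | out$region == fc$region)
        mu[hit] <- mu[hit] * fc$fold
      }
    }
    # counts scale with area and the ROI's technical factor (nuisances the
    # normalization must undo)
    lambda <- mu * (out$area_um2 / 1e4) * out$control_factor
    out$count <- stats::rpois(nrow(out), lambda)
    out$is_isotype <- out$target %in% isos
    dplyr::select(out, "roi_id", "organ", "region", "area_um2",
                  "control_factor", "target", "count", "is_isotype")
  })
}
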