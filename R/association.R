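#' Cross-region Pearson correlation of subset densities
#'
#' For each immune subset (and optional organ-site stratum), the Pearson
#' correlation across samples between its density in two histologic regions.
#' Correlations are computed on raw densities by default (`log = TRUE` uses
#' the log-density column). Cells of the matrix with fewer than 3 complete
#' samples or a constant variable are missing, with the reason recorded.
#'
#' @param density A density tibble (rows from [density_table()], any number of
#'   samples; an `organ` column enables stratification).
#' @param region_a,region_b Band labels to correlate.
#' @param stratify Stratify by the `organ` column when present.
#' @param log Correlate log densities instead of raw.
#' @return Tidy tibble: `organ` (if stratified), `subset`, `region_a`,
#'   `region_b`, `pcc`, `n`, `reason` (`NA` when computed).
#' @export
region_pair_pcc <- function(density, region_a, region_b, stratify = TRUE,
                            log = FALSE) {
  assert_cols(density, c("sample_id", "band", "subset", "density"), "density")
  val <- if (log) "log_density" else "density"
  d <- density |>
    dplyr::filter(.data$band %in% c(region_a, region_b)) |>
    dplyr::mutate(value = .data[[val]],
                  organ = if ("organ" %in% names(density) && stratify) .data$organ else "all") |>
    dplyr::select("organ", "sample_id", "subset", "band", "value") |>
    tidyr::pivot_wider(names_from = "band", values_from = "value")
  if (!all(c(region_a, region_b) %in% names(d))) {
    rlang::abort("both regions must be present in the density table")
  }
  d |>
    dplyr::group_by(.data$organ, .data$subset) |>
    dplyr::summarise(res = list(safe_pcc(.data[[region_a]], .data[[region_b]])),
                     .groups = "drop") |>
    tidyr::unnest_wider("res") |>
    dplyr::mutate(region_a = region_a, region_b = region_b) |>
    dplyr::select("organ", "subset", "region_a", "region_b", "pcc", "n", "reason")
}

safe_pcc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) {
    return(list(pcc = NA_real_, n = n, reason = "fewer than 3 complete samples"))
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(pcc = NA_real_, n = n, reason = "constant variable"))
  }
  list(pcc = stats::cor(x[ok], y[ok]), n = n, reason = NA_character_)
}

#' Paired primary-metastasis R-squared
#'
#' Squared Pearson correlation, per subset, between per-patient densities in
#' the primary tumor and the paired metastasis within one region. Missing when
#' fewer than 3 complete pairs.
#'
#' @param density_primary,density_met Density tibbles carrying a `patient_id`
#'   column; rows are matched by patient within `region` and subset.
#' @param region Band to compare.
#' @return Tibble: `subset`, `region`, `r2`, `n`, `reason`.
#' @export
paired_site_r2 <- function(density_primary, density_met, region) {
  for (d in list(density_primary, density_met)) {
    assert_cols(d, c("patient_id", "band", "subset", "density"), "density table")
  }
  a <- dplyr::filter(density_primary, .data$band == region) |>
    dplyr::select("patient_id", "subset", primary = "density")
  b <- dplyr::filter(density_met, .data$band == region) |>
    dplyr::select("patient_id", "subset", met = "density")
  dplyr::inner_join(a, b, by = c("patient_id", "subset")) |>
    dplyr::group_by(.data$subset) |>
    dplyr::summarise(res = list(safe_pcc(.data$primary, .data$met)), .groups = "drop") |>
    tidyr::unnest_wider("res") |>
    dplyr::mutate(region = region, r2 = .data$pcc^2) |>
    dplyr::select("subset", "region", "r2", "n", "reason")
}

#' Correlation between aggregate abundance and sporadic densities
#'
#' Pearson correlation across samples between a per-sample aggregate summary
#' variable (intratumoral LA count by default) and the sporadic (non-
#' aggregated) density of each subset in each region.
#'
#' @param la_counts Tibble with `sample_id` and the aggregate variable
#'   (column named by `la_var`).
#' @param sporadic Density tibble of sporadic cells over the same samples.
#' @param la_var Name of the aggregate variable column.
#' @return Tidy tibble: `subset`, `band`, `pcc`, `n`, `reason`.
#' @export
la_immune_pcc <- function(la_counts, sporadic, la_var = "n_intratumoral_la") {
  assert_cols(la_counts, c("sample_id", la_var), "la_counts")
  assert_cols(sporadic, c("sample_id", "band", "subset", "density"), "sporadic")
  sporadic |>
    dplyr::inner_join(la_counts[, c("sample_id", la_var)], by = "sample_id") |>
    dplyr::group_by(.data$subset, .data$band) |>
    dplyr::summarise(res = list(safe_pcc(.data$density, .data[[la_var]])),
                     .groups = "drop") |>
    tidyr::unnest_wider("res") |>
    dplyr::select("subset", "band", "pcc", "n", "reason")
}

#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment
#'
#' Two-sided rank-sum tests between every pair of groups (e.g. organ sites)
#' within a declared family, BH-adjusted within that family. The exact null
#' distribution is used for combined n <= 20 without ties; otherwise the
#' normal approximation with tie correction.
#'
#' @param values Numeric vector of per-sample values.
#' @param groups Group labels (same length).
#' @param paired Use the signed-rank test on paired values (groups must then
#'   be aligned by position within each level).
#' @param exact_max Combined-n limit for the exact distribution.
#' @return Tibble of `TestResult` rows: `group_a`, `group_b`, `statistic`,
#'   `p`, `q`, `n_a`, `n_b`, `significance`.
#' @export
wilcoxon_bh <- function(values, groups, paired = FALSE, exact_max = 20) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2) rlang::abort("need at least two groups")
  combs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- purrr::map_dfr(combs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (!length(a) || !length(b)) {
      return(tibble::tibble(group_a = pr[1], group_b = pr[2],
                            statistic = NA_real_, p = NA_real_,
                            n_a = length(a), n_b = length(b)))
    }
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && (length(a) + length(b)) <= exact_max && !paired
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = exact, correct = FALSE))
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   statistic = unname(wt$statistic), p = wt$p.value,
                   n_a = length(a), n_b = length(b))
  })
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows$significance <- significance_stars(rows$q)
  rows
}

significance_stars <- function(q) {
  dplyr::case_when(is.na(q) ~ NA_character_,
                   q < 1e-4 ~ "****", q < 1e-3 ~ "***",
                   q < 1e-2 ~ "**", q < 0.05 ~ "*", TRUE ~ "ns")
}

#' Chi-squared test of aggregate presence across organs
#'
#' Pearson chi-squared test (no continuity correction) on a 2 x k table of
#' samples with/without intratumoral lymphoid aggregates per organ site.
#' Warns when any expected count is below 5.
#'
#' @param presence A 2 x k matrix (rows: with/without) or a data frame with
#'   `organ` and logical `present` columns to tabulate.
#' @return Tibble: `statistic`, `df`, `p`, plus the expected counts as an
#'   attribute `expected`.
#' @export
chi2_presence <- function(presence) {
  if (is.data.frame(presence)) {
    assert_cols(presence, c("organ", "present"), "presence")
    tab <- table(factor(presence$present, levels = c(TRUE, FALSE)), presence$organ)
  } else {
    tab <- as.matrix(presence)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || ncol(tab) < 2) {
    rlang::abort("presence table needs >= 2 non-empty columns and non-zero margins")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    rlang::warn("some expected counts are below 5; chi-squared approximation may be poor")
  }
  out <- tibble::tibble(statistic = unname(ct$statistic),
                        df = unname(ct$parameter), p = ct$p.value)
  attr(out, "expected") <- ct$expected
  out
}
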