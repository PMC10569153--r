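#' Infiltration archetype specification
#'
#' An archetype bundles everything the tissue simulator needs: per-subset
#' intensity profiles over signed boundary distance d (um, negative inside the
#' tumor), an aggregate-planting spec, and per-marker intensity-noise
#' distributions. The intensity profile is a logistic transition between an
#' intratumoral and an extratumoral plateau plus an optional Gaussian bump at
#' the invasive margin:
#' lambda(d) = base_in + (base_out - base_in) * plogis((d - mid)/slope)
#'           + bump * exp(-(d - bump_center)^2 / (2 * bump_sd^2)).
#' All parameters are cells/mm^2 (plateaus, bump) or um (mid, slope,
#' bump_center, bump_sd); lambda is everywhere non-negative by construction.
#'
#' @param name Archetype name.
#' @param profiles Tibble with columns `subset`, `base_in`, `base_out`, `mid`,
#'   `slope`, `bump`, `bump_center`, `bump_sd`.
#' @param aggregates List: `n`, `band_weights` (named, summing to 1),
#'   `cells_per_aggregate`, `sigma_um` (> 0), `composition` (named leaf
#'   fractions summing to 1), `gc_fraction` (BCL6+ probability among B-cell
#'   members), `pd1_fraction`.
#' @param functional List: `pd1` (PD-1 probability on background T/B cells),
#'   `pdl1` (PD-L1 probability on myeloid cells).
#' @param marker_noise Tibble from [default_marker_noise()].
#' @return An `archetype_spec`.
#' @export
archetype_spec <- function(name, profiles, aggregates = no_aggregates(),
                           functional = list(pd1 = 0.15, pdl1 = 0.2),
                           marker_noise = default_marker_noise()) {
  assert_cols(profiles, c("subset", "base_in", "base_out", "mid", "slope",
                          "bump", "bump_center", "bump_sd"), "profiles")
  if (any(profiles$base_in < 0 | profiles$base_out < 0 | profiles$bump < 0)) {
    rlang::abort("intensity profile plateaus and bumps must be non-negative")
  }
  if (any(profiles$slope <= 0 | profiles$bump_sd <= 0)) {
    rlang::abort("profile slope and bump_sd must be positive")
  }
  if (aggregates$n > 0) {
    if (abs(sum(aggregates$composition) - 1) > 1e-8) {
      rlang::abort("aggregate composition fractions must sum to 1")
    }
    if (abs(sum(aggregates$band_weights) - 1) > 1e-8) {
      rlang::abort("aggregate band weights must sum to 1")
    }
    if (aggregates$sigma_um <= 0) rlang::abort("aggregate sigma must be > 0")
  }
  structure(list(name = name, profiles = profiles, aggregates = aggregates,
                 functional = functional, marker_noise = marker_noise),
            class = "archetype_spec")
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf("<archetype_spec> '%s': %d subset profiles, %d aggregate(s)\n",
              x$name, nrow(x$profiles), x$aggregates$n))
  invisible(x)
}

no_aggregates <- function() {
  list(n = 0L, band_weights = c(outer_margin = 1), cells_per_aggregate = 0L,
       sigma_um = 40, composition = c(b_cell = 1), gc_fraction = 0,
       pd1_fraction = 0.3)
}

#' Evaluate an archetype intensity profile
#'
#' @param spec An `archetype_spec`.
#' @param subset Subset name present in the profiles.
#' @param d Signed distances (um).
#' @return lambda(d) in cells/mm^2.
#' @export
lambda_profile <- function(spec, subset, d) {
  p <- spec$profiles[spec$profiles$subset == subset, ]
  if (!nrow(p)) rlang::abort(sprintf("no profile for subset '%s'", subset))
  p$base_in + (p$base_out - p$base_in) * stats::plogis((d - p$mid) / p$slope) +
    p$bump * exp(-(d - p$bump_center)^2 / (2 * p$bump_sd^2))
}

profile_row <- function(subset, base_in, base_out, bump = 0, bump_center = 250,
                        bump_sd = 200, mid = 0, slope = 30) {
  tibble::tibble(subset = subset, base_in = base_in, base_out = base_out,
                 mid = mid, slope = slope, bump = bump,
                 bump_center = bump_center, bump_sd = bump_sd)
}

#' Organ-archetype presets
#'
#' Qualitative infiltration presets emulating the organ-specific patterns of
#' colorectal primary tumors and metastases: `primary_like` and `lung_like`
#' are infiltrated tissues (substantial intratumoral lymphocyte and APC
#' density; intratumoral aggregates, mature in primaries), `liver_like` is
#' peritumorally enriched / intratumorally excluded (lymphocytes concentrated
#' at the outer invasive margin, M2-skewed macrophages, peritumoral
#' aggregates lacking germinal centers), and `peritoneal_like` is sparsely
#' infiltrated throughout. The presets encode rank orderings between organs,
#' not calibrated magnitudes.
#'
#' @param name One of `"primary_like"`, `"lung_like"`, `"liver_like"`,
#'   `"peritoneal_like"`.
#' @return An `archetype_spec`.
#' @export
archetype_preset <- function(name = c("primary_like", "lung_like", "liver_like",
                                      "peritoneal_like")) {
  name <- rlang::arg_match(name)
  common <- dplyr::bind_rows(
    profile_row("tumor", 600, 0, slope = 20),
    profile_row("other", 120, 120))
  # base_out is the distal plateau; the Gaussian bump centred just outside the
  # boundary supplies the peritumoral (outer-margin / juxtatumoral) enrichment
  # that decays toward distal tissue.
  pr <- switch(name,
    lung_like = dplyr::bind_rows(common,
      profile_row("cd4_t", 120, 40, bump = 80, bump_center = 300, bump_sd = 400),
      profile_row("cd8_t", 100, 35, bump = 60, bump_center = 300, bump_sd = 400),
      profile_row("treg", 25, 8, bump = 12), profile_row("tfh", 8, 3, bump = 4),
      profile_row("cd4_activated", 30, 8, bump = 15),
      profile_row("cd4_tcf1", 60, 15, bump = 20),
      profile_row("cd8_activated", 25, 8, bump = 12),
      profile_row("cd8_stem", 50, 12, bump = 15),
      profile_row("b_cell", 60, 20, bump = 30), profile_row("gd_t", 10, 4, bump = 4),
      profile_row("m1_tam", 40, 15, bump = 10), profile_row("m2_tam", 30, 15, bump = 10),
      profile_row("tan", 20, 10, bump = 5), profile_row("apc", 120, 30, bump = 30)),
    primary_like = dplyr::bind_rows(common,
      profile_row("cd4_t", 100, 40, bump = 80, bump_center = 300, bump_sd = 400),
      profile_row("cd8_t", 90, 35, bump = 60, bump_center = 300, bump_sd = 400),
      profile_row("treg", 30, 8, bump = 15), profile_row("tfh", 10, 4, bump = 5),
      profile_row("cd4_activated", 25, 8, bump = 12),
      profile_row("cd4_tcf1", 50, 15, bump = 18),
      profile_row("cd8_activated", 20, 8, bump = 10),
      profile_row("cd8_stem", 40, 12, bump = 12),
      profile_row("b_cell", 55, 20, bump = 35), profile_row("gd_t", 8, 4, bump = 4),
      profile_row("m1_tam", 35, 15, bump = 10), profile_row("m2_tam", 30, 15, bump = 10),
      profile_row("tan", 20, 10, bump = 5), profile_row("apc", 100, 30, bump = 25)),
    liver_like = dplyr::bind_rows(common,
      profile_row("cd4_t", 15, 30, bump = 150), profile_row("cd8_t", 10, 25, bump = 120),
      profile_row("treg", 4, 6, bump = 30), profile_row("tfh", 1, 2, bump = 4),
      profile_row("cd4_activated", 6, 8, bump = 40),
      profile_row("cd4_tcf1", 6, 8, bump = 20),
      profile_row("cd8_activated", 5, 8, bump = 30),
      profile_row("cd8_stem", 6, 8, bump = 15),
      profile_row("b_cell", 8, 15, bump = 60), profile_row("gd_t", 2, 3, bump = 4),
      profile_row("m1_tam", 15, 10, bump = 10), profile_row("m2_tam", 45, 20, bump = 15),
      profile_row("tan", 25, 12, bump = 8), profile_row("apc", 20, 15, bump = 30)),
    peritoneal_like = dplyr::bind_rows(common,
      profile_row("cd4_t", 12, 10, bump = 15), profile_row("cd8_t", 10, 8, bump = 12),
      profile_row("treg", 4, 2, bump = 4), profile_row("tfh", 1, 1, bump = 1),
      profile_row("cd4_activated", 3, 2, bump = 3),
      profile_row("cd4_tcf1", 5, 3, bump = 4),
      profile_row("cd8_activated", 3, 2, bump = 3),
      profile_row("cd8_stem", 5, 3, bump = 4),
      profile_row("b_cell", 8, 5, bump = 6), profile_row("gd_t", 2, 1, bump = 1),
      profile_row("m1_tam", 15, 8, bump = 5), profile_row("m2_tam", 35, 15, bump = 8),
      profile_row("tan", 25, 12, bump = 8), profile_row("apc", 15, 8, bump = 8)))
  aggs <- switch(name,
    primary_like = list(n = 3L,
      band_weights = c(core = 0.2, inner_margin = 0.2, outer_margin = 0.4, juxta = 0.2),
      cells_per_aggregate = 180L, sigma_um = 40,
      composition = c(b_cell = 0.45, cd4_t = 0.18, cd8_t = 0.12, tfh = 0.15,
                      cd4_tcf1 = 0.05, cd8_stem = 0.05),
      gc_fraction = 0.35, pd1_fraction = 0.4),
    lung_like = list(n = 3L,
      band_weights = c(core = 0.35, inner_margin = 0.35, outer_margin = 0.2, juxta = 0.1),
      cells_per_aggregate = 150L, sigma_um = 40,
      composition = c(b_cell = 0.42, cd4_t = 0.25, cd8_t = 0.15, tfh = 0.03,
                      cd4_tcf1 = 0.1, cd8_stem = 0.05),
      gc_fraction = 0.02, pd1_fraction = 0.3),
    liver_like = list(n = 2L,
      band_weights = c(outer_margin = 0.6, juxta = 0.4),
      cells_per_aggregate = 120L, sigma_um = 40,
      composition = c(b_cell = 0.45, cd4_t = 0.27, cd8_t = 0.15, tfh = 0.03,
                      cd4_tcf1 = 0.05, cd8_stem = 0.05),
      gc_fraction = 0.02, pd1_fraction = 0.3),
    peritoneal_like = list(n = 1L,
      band_weights = c(outer_margin = 0.5, juxta = 0.5),
      cells_per_aggregate = 80L, sigma_um = 40,
      composition = c(b_cell = 0.45, cd4_t = 0.27, cd8_t = 0.15, tfh = 0.03,
                      cd4_tcf1 = 0.05, cd8_stem = 0.05),
      gc_fraction = 0.02, pd1_fraction = 0.3))
  archetype_spec(name, pr, aggs)
}

# Ground-truth marker sets per terminal subset label.
leaf_markers <- function() {
  list(tumor = "CK20",
       treg = c("CD3", "CD4", "FOXP3"),
       tfh = c("CD3", "CD4", "BCL6"),
       cd4_activated = c("CD3", "CD4", "HLADR"),
       cd4_tcf1 = c("CD3", "CD4", "TCF1"),
       cd8_activated = c("CD3", "CD8", "HLADR"),
       cd8_stem = c("CD3", "CD8", "TCF1"),
       cd4_t = c("CD3", "CD4"),
       cd8_t = c("CD3", "CD8"),
       gd_t = c("CD3", "TCRd"),
       b_cell = "CD20",
       m1_tam = "CD68",
       m2_tam = c("CD68", "CD163"),
       tan = "CD66b",
       apc = "HLADR",
       other = character(0))
}

all_markers <- function() {
  unique(c(unlist(leaf_markers()), "PD1", "PDL1"))
}

#' Default marker intensity-noise specification
#'
#' Positive and negative intensity distributions (normal, arbitrary units)
#' per marker, with well-separated defaults; thresholds at the midpoint
#' recover ground truth with negligible error.
#'
#' @param markers Marker names.
#' @param mu_neg,sd_neg,mu_pos,sd_pos Distribution parameters recycled over
#'   markers.
#' @return Tibble with one row per marker.
#' @export
default_marker_noise <- function(markers = all_markers(), mu_neg = 1,
                                 sd_neg = 1, mu_pos = 8, sd_pos = 1.5) {
  tibble::tibble(marker = markers, mu_neg = mu_neg, sd_neg = sd_neg,
                 mu_pos = mu_pos, sd_pos = sd_pos)
}

#' Midpoint thresholds for a marker-noise spec
#' @param noise_spec From [default_marker_noise()].
#' @return Named numeric vector of thresholds.
#' @export
default_thresholds <- function(noise_spec = default_marker_noise()) {
  stats::setNames((noise_spec$mu_neg + noise_spec$mu_pos) / 2, noise_spec$marker)
}
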