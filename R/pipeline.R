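#' Validated run configuration
#'
#' Collects every tunable the pipeline uses, with the field-standard defaults:
#' band cutoffs 0.5 / 2 / 5 mm, direct-contact radius 10 um, aggregate
#' clustering at eps 50 um / 20 cells, raster resolution 10 um, log
#' pseudocount 1 cell/mm^2.
#'
#' @param archetypes Named character vector or list mapping organ-site labels
#'   to archetype presets/specs (simulation input), or `NULL` when reading
#'   files.
#' @param n_samples Samples per organ site (recycled).
#' @param seed Master integer seed.
#' @param cutoffs Band cutoffs (um), strictly increasing.
#' @param radius_um Proximity radius (um), > 0.
#' @param eps_um,min_cells Aggregate-detection parameters.
#' @param resolution Raster resolution (um).
#' @param pseudocount Log-density pseudocount.
#' @param pcc_log Correlate log densities in the association stage.
#' @param out Optional output directory.
#' @param geometry_args List passed to [make_geometry()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(archetypes = c(lung = "lung_like", liver = "liver_like"),
                       n_samples = 12, seed = 1,
                       cutoffs = c(500, 2000, 5000), radius_um = 10,
                       eps_um = 50, min_cells = 20, resolution = 10,
                       pseudocount = 1, pcc_log = FALSE, out = NULL,
                       geometry_args = list()) {
  if (length(cutoffs) != 3 || any(diff(cutoffs) <= 0)) {
    rlang::abort("band cutoffs must be three strictly increasing values")
  }
  if (radius_um <= 0) rlang::abort("proximity radius must be > 0")
  if (eps_um <= 0 || min_cells < 3) rlang::abort("need eps_um > 0 and min_cells >= 3")
  if (resolution <= 0) rlang::abort("resolution must be > 0")
  structure(list(archetypes = archetypes, n_samples = n_samples, seed = seed,
                 cutoffs = cutoffs, radius_um = radius_um, eps_um = eps_um,
                 min_cells = min_cells, resolution = resolution,
                 pseudocount = pseudocount, pcc_log = pcc_log, out = out,
                 geometry_args = geometry_args),
            class = "run_config")
}

#' Analyze one sample end to end
#'
#' Gates the cell table, compartmentalizes it against the geometry, and
#' computes the per-sample outputs: density and fraction tables, APC/T-cell
#' mutual availability, lymphoid-aggregate detection and per-band summary,
#' and the headline per-sample metrics (core lymphocyte density, core APC->T
#' availability, intratumoral aggregate count).
#'
#' @param cells Cell table with boolean marker columns (e.g.
#'   `tissue$cells` from [simulate_tissue()]).
#' @param geometry The sample's [tissue_geometry()].
#' @param config A [run_config()].
#' @param gating A `gating_config`.
#' @param field Optional precomputed [distance_field()].
#' @param sample_id Sample label.
#' @return List: `map`, `density`, `fractions`, `availability`, `las`,
#'   `la_summary`, `metrics`.
#' @export
analyze_sample <- function(cells, geometry, config = run_config(),
                           gating = default_gating_config(), field = NULL,
                           sample_id = NULL) {
  sid <- sample_id %||% (if ("sample_id" %in% names(cells)) cells$sample_id[1] else "sample1")
  cells <- assign_phenotype(cells, gating)
  map <- compartmentalize(cells, geometry, cutoffs = config$cutoffs,
                          resolution = config$resolution, field = field)
  map$cells <- cache_membership(map$cells, gating)
  dens <- density_table(map = map, config = gating,
                        pseudocount = config$pseudocount, sample_id = sid)
  fracs <- dplyr::bind_rows(
    fraction_table(map = map, numerator = "treg", denominator = "cd4_t",
                   config = gating, sample_id = sid),
    fraction_table(map = map, denominator = "cd4_t", flag = "pd1",
                   config = gating, sample_id = sid),
    fraction_table(map = map, denominator = "cd8_t", flag = "pd1",
                   config = gating, sample_id = sid))
  avail <- mutual_availability(map = map, source = "apc", target = "cd8_stem",
                               r = config$radius_um, config = gating,
                               sample_id = sid)
  las <- detect_aggregates(map$cells, eps_um = config$eps_um,
                           min_cells = config$min_cells, config = gating)
  la_sum <- summarize_aggregates(las, map, sample_id = sid)
  metrics <- sample_metrics(map, las, la_sum, config, gating, sid)
  list(map = map, density = dens, fractions = fracs, availability = avail,
       las = las, la_summary = la_sum, metrics = metrics)
}

# Headline per-sample metrics used by the cohort-level comparisons.
sample_metrics <- function(map, las, la_sum, config, gating, sid) {
  cells <- map$cells
  memb <- membership_long(cells, gating)
  lymph_rows <- unique(memb$row[memb$subset %in% c("cd4_t", "cd8_t", "gd_t", "b_cell")])
  core_area <- map$areas$area_mm2[map$areas$band == "core"]
  core_lymph <- sum(cells$band[lymph_rows] == "core") /
    ifelse(core_area > 0, core_area, NA_real_)
  apc_rows <- unique(memb$row[memb$subset == "apc"])
  t_rows <- unique(memb$row[memb$subset %in% c("cd4_tcf1", "cd8_stem")])
  apc_core <- cells[intersect(apc_rows, which(cells$band == "core")), ]
  apc_t <- if (nrow(apc_core)) {
    mean(neighbor_counts(apc_core, cells[t_rows, ], config$radius_um))
  } else NA_real_
  n_intra <- sum(la_sum$per_band$n_aggregates[la_sum$per_band$band %in%
                                                c("core", "inner_margin")])
  tibble::tibble(sample_id = sid,
                 core_lymphocyte_density = core_lymph,
                 core_apc_t_availability = apc_t,
                 n_intratumoral_la = n_intra,
                 n_aggregates = nrow(las$aggregates),
                 n_mature_tls = sum(las$aggregates$maturity == "mature_TLS"))
}

#' Run the full pipeline over simulated cohorts
#'
#' Simulates one cohort per organ-site archetype, analyzes every sample
#' ([analyze_sample()]), assembles cohort-level tables, and runs the
#' association stage: pairwise rank-sum tests (BH-adjusted within each
#' band x subset family) on densities between organ sites, cross-region
#' correlations, and the chi-squared test of intratumoral aggregate presence.
#' Writes all tables plus a manifest when `config$out` is set.
#'
#' @param config A [run_config()].
#' @param gating A `gating_config`.
#' @return List of tidy tables: `metrics`, `densities`, `fractions`,
#'   `availability`, `la_per_band`, `la_presence`, `tests`, `region_pcc`,
#'   `presence_test`, plus `manifest` when written.
#' @export
run_pipeline <- function(config = run_config(), gating = default_gating_config()) {
  organs <- names(config$archetypes) %||% as.character(config$archetypes)
  n_each <- rep(config$n_samples, length.out = length(organs))
  results <- list()
  for (k in seq_along(organs)) {
    spec <- config$archetypes[[k]]
    tissues <- do.call(simulate_cohort,
                       c(list(spec, n_each[k], seed = child_seed(config$seed, k),
                              resolution = config$resolution),
                         config$geometry_args))
    for (tis in tissues) {
      res <- analyze_sample(tis$cells, tis$geometry, config, gating,
                            field = tis$field)
      res$organ <- organs[k]
      results[[length(results) + 1]] <- res
    }
  }
  organ_of <- vapply(results, function(r) r$organ, character(1))
  bind_stage <- function(get) {
    purrr::map2_dfr(results, organ_of, function(r, o) dplyr::mutate(get(r), organ = o))
  }
  metrics <- bind_stage(function(r) r$metrics)
  densities <- bind_stage(function(r) r$density)
  fractions <- bind_stage(function(r) r$fractions)
  availability <- bind_stage(function(r) r$availability)
  la_per_band <- bind_stage(function(r) r$la_summary$per_band)
  la_presence <- tibble::tibble(
    sample_id = metrics$sample_id, organ = metrics$organ,
    present = metrics$n_intratumoral_la > 0)
  tests <- densities |>
    dplyr::group_by(.data$band, .data$subset) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$organ) < 2) return(tibble::tibble())
      wilcoxon_bh(d$density, d$organ)
    }) |>
    dplyr::ungroup()
  region_pcc <- region_pair_pcc(densities, "inner_margin", "outer_margin")
  presence_test <- if (length(unique(la_presence$organ)) >= 2 &&
                       length(unique(la_presence$present)) == 2) {
    chi2_presence(la_presence)
  } else NULL
  out <- list(metrics = metrics, densities = densities, fractions = fractions,
              availability = availability, la_per_band = la_per_band,
              la_presence = la_presence, tests = tests,
              region_pcc = region_pcc, presence_test = presence_test)
  if (!is.null(config$out)) {
    tabs <- out[!vapply(out, is.null, logical(1))]
    tabs <- tabs[vapply(tabs, is.data.frame, logical(1))]
    out$manifest <- write_results(tabs, config$out,
                                  settings = unclass(config)[setdiff(names(config), "out")],
                                  seed = config$seed)
  }
  out
}

#' Organ-signature comparison between two simulated cohorts
#'
#' Simulates two cohorts (default: lung-like vs liver-like), and tests the
#' three qualitative organ signatures on the per-sample metrics: core
#' lymphocyte density, core APC/T-cell mutual availability, and intratumoral
#' lymphoid-aggregate count, each compared between arms with a two-sided
#' rank-sum test and BH-adjusted as one family of three.
#'
#' @param seed Integer seed for the pair of cohorts.
#' @param n_per_arm Samples per cohort.
#' @param arms Two archetype preset names.
#' @param config A [run_config()] supplying the analysis parameters.
#' @return Tibble: `metric`, `median_a`, `median_b`, `p`, `q`,
#'   `direction` (`median_a - median_b` sign).
#' @export
cohort_signature <- function(seed = 1, n_per_arm = 20,
                             arms = c("lung_like", "liver_like"),
                             config = run_config(resolution = 20,
                                                 geometry_args = list(
                                                   extent_um = 13200,
                                                   tumor_radius_um = 1200))) {
  config$archetypes <- stats::setNames(as.list(arms), arms)
  config$n_samples <- n_per_arm
  config$seed <- seed
  config$out <- NULL
  run <- run_pipeline(config)
  m <- run$metrics
  one <- function(col) {
    a <- m[[col]][m$organ == arms[1]]; b <- m[[col]][m$organ == arms[2]]
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
    tibble::tibble(metric = col, median_a = stats::median(a, na.rm = TRUE),
                   median_b = stats::median(b, na.rm = TRUE), p = p)
  }
  res <- dplyr::bind_rows(one("core_lymphocyte_density"),
                          one("core_apc_t_availability"),
                          one("n_intratumoral_la"))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$direction <- sign(res$median_a - res$median_b)
  res
}
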