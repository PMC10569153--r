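#' Default hierarchical gating configuration
#'
#' The default gate set reproduces the standard four-panel mIF lineage
#' hierarchy for colorectal tumors: 14 immune subsets plus `tumor` (CK20+) and
#' `other`. Marker names are the syntactic forms of the panel antibodies
#' (HLA-DR -> `HLADR`, TCR-delta -> `TCRd`). Each rule names its
#' required-positive and required-negative markers, its parent gate, its panel
#' (1-4), and a leaf priority used for deterministic first-match labelling.
#'
#' Subsets: total CD4 and CD8 T cells and their subsets (FOXP3+ Tregs, BCL6+
#' Tfh, HLA-DR+ activated T cells, TCF1+ T cells / stem-like CD8), B cells,
#' gamma-delta T cells, M1/M2 tumor-associated macrophages, tumor-associated
#' neutrophils, and antigen-presenting cells (lineage-negative HLA-DR+, the
#' lineage cocktail here being CD3/CD20/CD68/CD66b/CK20).
#'
#' @param m2_requires_cd68 If `FALSE`, CD68-CD163+ cells also gate as M2 TAM
#'   (the default requires CD68+CD163+ for M2 and CD68+CD163- for M1).
#' @param tumor_precedence If `TRUE` (default) CK20+ cells are labelled
#'   `tumor` regardless of immune markers, so spillover double-positives do
#'   not inflate immune counts.
#' @return A `gating_config`: tibble of rules with class attributes.
#' @export
default_gating_config <- function(m2_requires_cd68 = TRUE, tumor_precedence = TRUE) {
  r <- function(name, requires, excludes, parent, panel, priority, functional = NA) {
    tibble::tibble(name = name, requires = list(requires), excludes = list(excludes),
                   parent = parent, panel = panel, priority = priority,
                   functional = functional)
  }
  lin <- c("CD3", "CD20", "CD68", "CD66b", "CK20")
  m2_req <- if (m2_requires_cd68) c("CD68", "CD163") else "CD163"
  rules <- dplyr::bind_rows(
    r("tumor",         "CK20",                  character(0), NA,      NA_integer_, 0),
    r("treg",          c("CD3", "CD4", "FOXP3"), "CK20",      "cd4_t", 1L, 10, "PD1"),
    r("tfh",           c("CD4", "BCL6"),         "CK20",      "cd4_t", 4L, 11, "PD1"),
    r("cd4_activated", c("CD4", "HLADR"),        "CK20",      "cd4_t", 4L, 12, "PD1"),
    r("cd4_tcf1",      c("CD4", "TCF1"),         "CK20",      "cd4_t", 4L, 13, "PD1"),
    r("cd8_activated", c("CD8", "HLADR"),        "CK20",      "cd8_t", 4L, 14, "PD1"),
    r("cd8_stem",      c("CD8", "TCF1"),         "CK20",      "cd8_t", 4L, 15, "PD1"),
    r("cd4_t",         c("CD3", "CD4"),          "CK20",      NA,      1L, 20, "PD1"),
    r("cd8_t",         c("CD3", "CD8"),          "CK20",      NA,      1L, 21, "PD1"),
    r("gd_t",          "TCRd",                   "CK20",      NA,      3L, 22, "PD1"),
    r("b_cell",        "CD20",                   "CK20",      NA,      3L, 23, "PD1"),
    r("m2_tam",        m2_req,                   "CK20",      NA,      2L, 30, "PDL1"),
    r("m1_tam",        "CD68",                  c("CD163", "CK20"), NA, 2L, 31, "PDL1"),
    r("tan",           "CD66b",                  "CK20",      NA,      2L, 32, "PDL1"),
    r("apc",           "HLADR",                  lin,         NA,      4L, 40, NA)
  )
  if (!tumor_precedence) {
    rules$excludes <- lapply(rules$excludes, setdiff, "CK20")
    rules$priority[rules$name == "tumor"] <- 99
  }
  structure(rules, class = c("gating_config", class(rules)),
            tumor_precedence = tumor_precedence)
}

#' The immune subsets defined by a gating config
#'
#' @param config A `gating_config`.
#' @return Character vector of immune subset names (excluding `tumor` and
#'   `other`), in hierarchy order.
#' @export
immune_subsets <- function(config = default_gating_config()) {
  setdiff(config$name, c("tumor", "other"))
}

#' All markers referenced by a gating config
#' @param config A `gating_config`.
#' @return Character vector of marker names.
#' @export
gating_markers <- function(config = default_gating_config()) {
  unique(c(unlist(config$requires), unlist(config$excludes),
           stats::na.omit(config$functional)))
}

#' Threshold continuous marker intensities into boolean calls
#'
#' For each marker in `thresholds`, reads the `<marker>_int` intensity column
#' and writes a logical `<marker>` column: positive when intensity >= the
#' threshold (ties are positive).
#'
#' @param cells Cell table with `<marker>_int` columns.
#' @param thresholds Named numeric vector of per-marker thresholds.
#' @return `cells` with logical marker columns added/overwritten.
#' @export
threshold_markers <- function(cells, thresholds) {
  cells <- tibble::as_tibble(cells)
  missing <- setdiff(paste0(names(thresholds), "_int"), names(cells))
  if (length(missing)) {
    rlang::abort(paste0("no intensity column for marker(s): ",
                        paste(sub("_int$", "", missing), collapse = ", ")))
  }
  for (m in names(thresholds)) {
    cells[[m]] <- cells[[paste0(m, "_int")]] >= thresholds[[m]]
  }
  cells
}

rule_matches <- function(cells, requires, excludes) {
  ok <- rep(TRUE, nrow(cells))
  for (m in requires) ok <- ok & as.logical(cells[[m]])
  for (m in excludes) ok <- ok & !as.logical(cells[[m]])
  ok
}

#' Assign cell phenotypes by hierarchical gating
#'
#' Labels every cell with exactly one terminal subset via deterministic
#' first-match over the gate hierarchy (most specific gates first); cells
#' matching no gate become `other`. Also records hierarchical membership in
#' every subset a cell's markers satisfy (so a Treg counts in total CD4 T),
#' and the functional flags: PD-1 positivity is evaluated on T and B cells,
#' PD-L1 positivity on macrophages and neutrophils.
#'
#' @param cells Cell table with logical marker columns (see
#'   [threshold_markers()] for continuous input).
#' @param config A `gating_config`.
#' @param panel Restrict gating to one panel's rules (1-4), or `NULL`
#'   (default) to gate over all markers at once (single-table synthetic path).
#' @return `cells` with `subset` (factor), `pd1`, `pdl1` columns added.
#' @export
assign_phenotype <- function(cells, config = default_gating_config(), panel = NULL) {
  cells <- tibble::as_tibble(cells)
  rules <- config
  if (!is.null(panel)) rules <- rules[is.na(rules$panel) | rules$panel == panel, ]
  mk <- gating_markers(rules)
  missing <- setdiff(setdiff(mk, c("PD1", "PDL1")), names(cells))
  if (length(missing)) {
    rlang::abort(paste0("cells table lacks marker column(s): ",
                        paste(missing, collapse = ", ")))
  }
  rules <- rules[order(rules$priority), ]
  lab <- rep(NA_character_, nrow(cells))
  for (i in seq_len(nrow(rules))) {
    hit <- is.na(lab) & rule_matches(cells, rules$requires[[i]], rules$excludes[[i]])
    lab[hit] <- rules$name[i]
  }
  lab[is.na(lab)] <- "other"
  cells$subset <- factor(lab, levels = subset_levels(config))
  pd1 <- if ("PD1" %in% names(cells)) as.logical(cells$PD1) else rep(FALSE, nrow(cells))
  pdl1 <- if ("PDL1" %in% names(cells)) as.logical(cells$PDL1) else rep(FALSE, nrow(cells))
  memb <- subset_membership(cells, config)
  lymphoid <- rowSums(memb[, intersect(colnames(memb),
                                       c("cd4_t", "cd8_t", "gd_t", "b_cell")), drop = FALSE]) > 0
  myeloid <- rowSums(memb[, intersect(colnames(memb),
                                      c("m1_tam", "m2_tam", "tan")), drop = FALSE]) > 0
  cells$pd1 <- pd1 & lymphoid
  cells$pdl1 <- pdl1 & myeloid
  cells
}

subset_levels <- function(config = default_gating_config()) {
  c(config$name[order(config$priority)], "other")
}

#' Hierarchical subset membership matrix
#'
#' A cell belongs to every subset whose gate (required-positive and
#' required-negative markers) it satisfies, independent of its terminal label:
#' e.g. a FOXP3+ CD4 T cell is a member of both `treg` and `cd4_t`. This is
#' the membership used for all counting, so child counts never exceed parents.
#'
#' @inheritParams assign_phenotype
#' @return Logical matrix, cells x subsets (including `tumor`).
#' @export
subset_membership <- function(cells, config = default_gating_config()) {
  m <- vapply(seq_len(nrow(config)), function(i) {
    rule_matches(cells, config$requires[[i]], config$excludes[[i]])
  }, logical(nrow(cells)))
  if (nrow(cells) == 1L) m <- matrix(m, nrow = 1)
  if (nrow(cells) == 0L) m <- matrix(logical(0), 0, nrow(config))
  colnames(m) <- config$name
  m
}
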