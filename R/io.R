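#' Read a cell table
#'
#' Reads a delimited cell table (tab by default, dot decimal), validates the
#' schema and rejects malformed data rather than coercing it: duplicate cell
#' ids and non-finite coordinates are errors naming the offending rows.
#' Unknown columns are carried through untouched and row order is preserved.
#'
#' @param path File path.
#' @param required Required column names.
#' @param delim Field delimiter.
#' @return A tibble.
#' @export
read_cells <- function(path, required = c("cell_id", "x_um", "y_um"),
                       delim = "\t") {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  cells <- tibble::as_tibble(utils::read.delim(path, sep = delim,
                                               check.names = FALSE,
                                               stringsAsFactors = FALSE))
  assert_cols(cells, required, "cell table")
  dup <- cells$cell_id[duplicated(cells$cell_id)]
  if (length(dup)) {
    rlang::abort(paste0("duplicated cell_id(s): ",
                        paste(unique(dup), collapse = ", ")))
  }
  for (col in c("x_um", "y_um")) {
    if (!is.numeric(cells[[col]])) {
      rlang::abort(paste0("column ", col, " is not numeric"))
    }
    bad <- which(!is.finite(cells[[col]]))
    if (length(bad)) {
      rlang::abort(sprintf("non-finite %s at row(s): %s", col,
                           paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  cells
}

#' Write a cell table
#'
#' Tab-delimited, dot decimal, header preserved; logical marker columns are
#' written as TRUE/FALSE and factors as their labels so a write-read round
#' trip reproduces the table.
#'
#' @param cells Cell table.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path, delim = "\t") {
  out <- as.data.frame(cells)
  for (i in seq_along(out)) if (is.factor(out[[i]])) out[[i]] <- as.character(out[[i]])
  out <- out[, !vapply(out, is.list, logical(1)), drop = FALSE]
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tissue geometry from GeoJSON
#'
#' Expects a FeatureCollection of polygons in um coordinates, each feature
#' tagged with a `role` property of `"tumor"` or `"necrosis"`. Polygons are
#' validated (closed, simple); self-intersecting rings and missing role tags
#' are errors. Necrosis polygons lying entirely outside the tumor are dropped
#' with a warning (partial overlaps are clipped downstream by the raster).
#'
#' @param path GeoJSON file.
#' @return A [tissue_geometry()].
#' @export
read_geometry <- function(path) {
  js <- jsonlite::read_json(path)
  if (is.null(js$features)) rlang::abort("GeoJSON must be a FeatureCollection")
  tumor <- list(); necrosis <- list()
  for (f in js$features) {
    role <- f$properties$role
    if (is.null(role)) rlang::abort("every feature needs a 'role' property (tumor/necrosis)")
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    poly <- as_polygon(poly)
    if (!polygon_is_simple(poly)) {
      rlang::abort(sprintf("self-intersecting %s polygon in %s", role, path))
    }
    if (role == "tumor") tumor <- c(tumor, list(poly))
    else if (role == "necrosis") necrosis <- c(necrosis, list(poly))
    else rlang::abort(paste0("unknown polygon role: ", role))
  }
  if (!length(tumor)) rlang::abort("no tumor polygon in geometry file")
  extent <- if (!is.null(js$bbox)) {
    bb <- unlist(js$bbox); c(bb[1], bb[3], bb[2], bb[4])
  } else {
    all <- do.call(rbind, tumor)
    pad <- 5000
    c(min(all[, 1]) - pad, max(all[, 1]) + pad, min(all[, 2]) - pad, max(all[, 2]) + pad)
  }
  keep <- vapply(necrosis, function(p) {
    any(point_in_any(p[, 1], p[, 2], tumor))
  }, logical(1))
  if (any(!keep)) {
    rlang::warn(sprintf("%d necrosis polygon(s) entirely outside the tumor dropped",
                        sum(!keep)))
  }
  tissue_geometry(tumor, extent, necrosis = necrosis[keep])
}

#' Write tissue geometry as GeoJSON
#'
#' @param geometry A [tissue_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  feat <- function(poly, role) {
    ring <- lapply(seq_len(nrow(poly)), function(i) list(poly[i, 1], poly[i, 2]))
    ring <- c(ring, ring[1])  # close the ring
    list(type = "Feature", properties = list(role = role),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  ext <- geometry$extent
  js <- list(type = "FeatureCollection",
             bbox = list(ext[1], ext[3], ext[2], ext[4]),
             features = c(lapply(geometry$tumor, feat, role = "tumor"),
                          lapply(geometry$necrosis, feat, role = "necrosis")))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write gating configuration to YAML
#' @param config A `gating_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gating_config <- function(config, path) {
  rules <- lapply(seq_len(nrow(config)), function(i) {
    list(name = config$name[i],
         requires = as.list(config$requires[[i]]),
         excludes = as.list(config$excludes[[i]]),
         parent = if (is.na(config$parent[i])) NULL else config$parent[i],
         panel = if (is.na(config$panel[i])) NULL else config$panel[i],
         priority = config$priority[i],
         functional = if (is.na(config$functional[i])) NULL else config$functional[i])
  })
  yaml::write_yaml(list(rules = rules), path)
  invisible(path)
}

#' Read gating configuration from YAML
#' @param path YAML file from [write_gating_config()].
#' @return A `gating_config`.
#' @export
read_gating_config <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- purrr::map_dfr(y$rules, function(r) {
    tibble::tibble(name = r$name,
                   requires = list(unlist(r$requires) %||% character(0)),
                   excludes = list(unlist(r$excludes) %||% character(0)),
                   parent = r$parent %||% NA_character_,
                   panel = as.integer(r$panel %||% NA),
                   priority = r$priority,
                   functional = r$functional %||% NA_character_)
  })
  if (anyDuplicated(rules$name)) rlang::abort("gating rule names must be unique")
  structure(rules, class = c("gating_config", class(rules)))
}

#' Write a result bundle with a run manifest
#'
#' Writes each tibble in `tables` as a tab-delimited file and a
#' `manifest.json` recording the package version, a hash of the settings in
#' force, the seed, and every setting itself, so two runs with the same
#' configuration produce identical manifests up to the timestamp.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param settings Named list of the settings in force.
#' @param seed The run seed.
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, dir, settings = list(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) rlang::abort(paste0("cannot create output dir: ", dir))
  for (nm in names(tables)) {
    write_cells(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  manifest <- list(
    package = "spatialmif",
    version = as.character(utils::packageVersion("spatialmif")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config_hash = rlang::hash(settings),
    settings = settings,
    tables = as.list(names(tables)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
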