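#' Write rectangles as a GeoJSON FeatureCollection
#'
#' Each row becomes a Polygon feature; all non-geometry columns are carried
#' as properties. Coordinates are the planar meter coordinates used
#' throughout (recorded in the collection's `crs_note` property rather than
#' pretending to be geographic).
#'
#' @param rects tibble with `xmin`, `xmax`, `ymin`, `ymax` plus property
#'   columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rects_geojson <- function(rects, path) {
  props <- setdiff(names(rects), c("xmin", "xmax", "ymin", "ymax"))
  features <- lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = as.list(r[props]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection",
             crs_note = "local projected plane, meters",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write points as a GeoJSON FeatureCollection
#'
#' @param pts tibble with `x`, `y` plus property columns.
#' @inheritParams write_rects_geojson
#' @export
write_points_geojson <- function(pts, path) {
  props <- setdiff(names(pts), c("x", "y"))
  features <- lapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    list(type = "Feature",
         properties = as.list(p[props]),
         geometry = list(type = "Point", coordinates = c(p$x, p$y)))
  })
  fc <- list(type = "FeatureCollection",
             crs_note = "local projected plane, meters",
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a region bundle to a directory of open formats
#'
#' Blocks, buildings, persons, and floodplains go to GeoJSON; the
#' elevation, tidal-offset, rise-rate, and water-mask grids to ESRI ASCII
#' rasters; and a key-value manifest records the configuration and seed so
#' the bundle can be regenerated bit-identically.
#'
#' @param bundle a `region_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_region_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rects_geojson(bundle$blocks, file.path(dir, "blocks.geojson"))
  write_points_geojson(bundle$buildings, file.path(dir, "buildings.geojson"))
  utils::write.csv(bundle$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE)
  write_rects_geojson(bundle$floodplains, file.path(dir, "floodplains.geojson"))
  write_grid_asc(bundle$elev, file.path(dir, "elevation.asc"))
  write_grid_asc(bundle$tidal, file.path(dir, "tidal_offset.asc"))
  write_grid_asc(bundle$rate, file.path(dir, "rise_rate.asc"))
  write_grid_asc(grid_like(bundle$elev, bundle$water * 1),
                 file.path(dir, "water_mask.asc"))
  write_manifest(bundle$config, file.path(dir, "manifest.txt"))
  invisible(dir)
}

# Flat key-value manifest; nested config entries are dotted paths.
write_manifest <- function(config, path, extra = list()) {
  flat <- unlist(config)
  lines <- c(
    sprintf("config_hash=%s", rlang::hash(config)),
    sprintf("%s=%s", names(flat), vapply(flat, format, "")),
    if (length(extra)) sprintf("%s=%s", names(extra),
                               vapply(extra, format, "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read the bundled example data tables
#'
#' Small published reference tables shipped with the package (per-county
#' decadal changes in population below 1 m of the 2020 sea level, and
#' hazard-zone emigration/population totals by subgroup), used as inputs to
#' the accounting and share arithmetic.
#'
#' @param name file name under the package's `extdata/`.
#' @return a tibble.
#' @export
read_reference_table <- function(name) {
  path <- system.file("extdata", name, package = "coastpop", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
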