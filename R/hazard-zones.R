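#' Elevation relative to the sea level of a given year
#'
#' Converts a ground-elevation grid referenced to a fixed vertical datum
#' into elevation relative to the local tidal datum (mean higher high water)
#' for a stated year: `E - T - r * (year - 1992) / 1000`, where `E` is
#' ground elevation (m), `T` the tidal-datum offset (m), and `r` the local
#' sea-level rise rate (mm/yr). 1992 is the midpoint of the tidal epoch to
#' which the offset surface refers, so the offset alone yields elevations
#' relative to the sea level of 1992 and multiples of the rate surface shift
#' them to other years. Nodata cells propagate.
#'
#' @param elev ground elevation `cp_grid` (m, fixed datum).
#' @param tidal tidal-datum offset `cp_grid` (m above the fixed datum).
#' @param rate sea-level rise rate `cp_grid` (mm/yr).
#' @param year target year of the sea level.
#' @return a `cp_grid` with attribute `sea_level_year`.
#' @export
relative_elevation_grid <- function(elev, tidal, rate, year) {
  check_coregistered(elev, tidal, rate, what = "elevation/tidal/rate grids")
  stopifnot_scalar_number(year, "year")
  g <- grid_like(elev, elev$values - tidal$values -
                   rate$values * (year - 1992) / 1000)
  attr(g, "sea_level_year") <- as.integer(year)
  g
}

#' Delineate dry land below a threshold elevation
#'
#' A cell belongs to the hazard zone iff its sea-level-relative elevation is
#' strictly below `z` meters (ties at exactly `z` are excluded) and it is
#' not open water or wetland. Membership is decided by the cell-center
#' value; the zone is represented as the set of member cells, which can be
#' exported as polygons with [zone_to_rects()].
#'
#' @param rel grid from [relative_elevation_grid()].
#' @param z threshold in meters above sea level; must be positive.
#' @param water_mask logical matrix (same shape as the grid), `TRUE` where
#'   open water or wetland.
#' @return an object of class `hazard_zone` with fields `mask`, `grid`
#'   (georeferencing), `zone_type = "elevation"`, `threshold_z_m`,
#'   `sea_level_year`, `coastal_flag`.
#' @export
delineate_low_land <- function(rel, z, water_mask) {
  stopifnot_scalar_number(z, "z", lo = 1e-12)
  if (!is.logical(water_mask) || !all(dim(water_mask) == dim(rel$values))) {
    abort("water_mask must be a logical matrix matching the grid shape")
  }
  if (all(is.na(rel$values))) {
    warn("relative elevation grid is all nodata; returning an empty zone")
  }
  mask <- !is.na(rel$values) & rel$values < z & !water_mask
  new_hazard_zone(mask, rel, zone_type = "elevation", threshold_z_m = z,
                  sea_level_year = attr(rel, "sea_level_year") %||% NA_integer_,
                  coastal_flag = NA_character_)
}

new_hazard_zone <- function(mask, grid, zone_type, threshold_z_m = NA_real_,
                            sea_level_year = NA_integer_,
                            coastal_flag = NA_character_) {
  structure(list(
    mask = mask,
    # georeferencing only (no values); compatible with cell_index() etc.
    grid = list(origin = grid$origin, cellsize = grid$cellsize,
                nx = grid$nx, ny = grid$ny),
    nx = grid$nx, ny = grid$ny,
    zone_type = zone_type, threshold_z_m = threshold_z_m,
    sea_level_year = sea_level_year, coastal_flag = coastal_flag
  ), class = "hazard_zone")
}

#' @export
print.hazard_zone <- function(x, ...) {
  cat(sprintf("<hazard_zone %s%s%s: %d cells, %.4g km2>\n",
              x$zone_type,
              if (!is.na(x$threshold_z_m)) sprintf(" z<%g m", x$threshold_z_m) else "",
              if (!is.na(x$coastal_flag)) paste0(" ", x$coastal_flag) else "",
              sum(x$mask), zone_area(x) / 1e6))
  invisible(x)
}

#' Total area of a hazard zone
#'
#' @param zone a `hazard_zone`.
#' @return area in square meters (cell count times cell area).
#' @export
zone_area <- function(zone) sum(zone$mask) * zone$grid$cellsize^2

#' Classify floodplain polygons as coastal or inland
#'
#' Each mapped floodplain polygon is assigned to the coastal class when the
#' area-majority of its cells has ground elevation at or below the base
#' flood elevation `bfe`, and to the inland class otherwise; zones are then
#' partitioned by category (A-like = 100-year, X500-like = 500-year) and
#' coastal flag. A polygon with no cells on the grid is classified inland
#' with a warning.
#'
#' @param flood_polys tibble of rectangles with columns `poly_id`,
#'   `category` (`"A"` or `"X500"`), `xmin`, `xmax`, `ymin`, `ymax`.
#' @param rel elevation `cp_grid` against which `bfe` is compared.
#' @param bfe base flood elevation in the same vertical reference as `rel`.
#' @return a list of `hazard_zone` objects, one per nonempty
#'   (category, coastal flag) combination.
#' @export
classify_floodplain <- function(flood_polys, rel, bfe) {
  stopifnot_scalar_number(bfe, "bfe")
  bad <- setdiff(unique(flood_polys$category), c("A", "X500"))
  if (length(bad)) {
    abort(sprintf("unknown floodplain categories: %s", paste(bad, collapse = ", ")))
  }
  flags <- character(nrow(flood_polys))
  masks <- vector("list", nrow(flood_polys))
  for (i in seq_len(nrow(flood_polys))) {
    m <- rect_cell_mask(rel, flood_polys$xmin[i], flood_polys$xmax[i],
                        flood_polys$ymin[i], flood_polys$ymax[i])
    masks[[i]] <- m
    n <- sum(m)
    if (n == 0L) {
      warn(sprintf("floodplain polygon %s lies outside the grid; classified inland",
                   flood_polys$poly_id[i]))
      flags[i] <- "inland"
    } else {
      flags[i] <- if (sum(rel$values[m] <= bfe, na.rm = TRUE) > n / 2) "coastal" else "inland"
    }
  }
  combos <- unique(data.frame(category = flood_polys$category, flag = flags,
                              stringsAsFactors = FALSE))
  zones <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    sel <- which(flood_polys$category == combos$category[k] & flags == combos$flag[k])
    mask <- Reduce(`|`, masks[sel])
    zones[[k]] <- new_hazard_zone(
      mask, rel,
      zone_type = if (combos$category[k] == "A") "floodplain_100" else "floodplain_500",
      coastal_flag = combos$flag[k])
  }
  names(zones) <- paste(vapply(zones, `[[`, "", "zone_type"), combos$flag, sep = "_")
  zones
}

#' Export a zone's cells as merged rectangles
#'
#' Greedily merges horizontal runs of member cells into rectangles, for
#' GeoJSON export and plotting. The union of the rectangles covers exactly
#' the member cells.
#'
#' @param zone a `hazard_zone`.
#' @return tibble with `xmin`, `xmax`, `ymin`, `ymax` (meters).
#' @export
zone_to_rects <- function(zone) {
  cs <- zone$grid$cellsize
  o <- zone$grid$origin
  out <- list()
  for (iy in seq_len(zone$ny)) {
    row <- zone$mask[, iy]
    if (!any(row)) next
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out[[length(out) + 1L]] <- tibble(
      xmin = o[1] + (starts[keep] - 1) * cs,
      xmax = o[1] + ends[keep] * cs,
      ymin = o[2] + (iy - 1) * cs,
      ymax = o[2] + iy * cs)
  }
  if (!length(out)) {
    return(tibble(xmin = numeric(), xmax = numeric(),
                  ymin = numeric(), ymax = numeric()))
  }
  dplyr::bind_rows(out)
}
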