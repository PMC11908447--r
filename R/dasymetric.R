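#' Per-block hazard-zone fractions
#'
#' For each census block, computes the fraction of its dry land inside the
#' zone (the uniform-density interpolation weight) and the fraction of its
#' buildings whose centroid falls inside the zone (the building-based
#' weight). Dry land is measured by cell-center membership against the water
#' mask; building membership is decided by the zone value of the cell
#' containing the building centroid. Blocks with no dry land are flagged and
#' given an area fraction of 0 with a warning.
#'
#' @param blocks tibble of block records for one census year: `block_id`,
#'   `county_id`, `xmin`, `xmax`, `ymin`, `ymax` (meters) and population
#'   columns.
#' @param zone a `hazard_zone`.
#' @param buildings tibble with building coordinates `x`, `y`.
#' @param water_mask logical matrix on the zone's grid, `TRUE` for water.
#' @return tibble with one row per block: `dry_area_m2`, `area_in_zone_m2`,
#'   `n_buildings`, `buildings_in_zone`, `fraction_area`,
#'   `fraction_buildings` (`NA` when the block has no buildings), and
#'   `zero_dry`.
#' @export
block_zone_fractions <- function(blocks, zone, buildings, water_mask) {
  check_blocks_on_grid(blocks, zone$grid)
  if (!all(dim(water_mask) == c(zone$nx, zone$ny))) {
    abort("water_mask shape does not match the zone grid")
  }
  braster <- block_cell_raster(zone$grid, blocks)
  dry <- !water_mask
  nb <- nrow(blocks)
  n_dry <- tabulate(braster[dry], nbins = nb)
  n_zone <- tabulate(braster[dry & zone$mask], nbins = nb)

  bcell <- cell_index(zone$grid, buildings$x, buildings$y)
  b_block <- assign_blocks(buildings$x, buildings$y, blocks)
  b_in <- !is.na(bcell) & zone$mask[ifelse(is.na(bcell), 1L, bcell)]
  bidx <- match(b_block, blocks$block_id)
  ok <- !is.na(bidx)
  n_bld <- tabulate(bidx[ok], nbins = nb)
  n_bld_in <- tabulate(bidx[ok & b_in], nbins = nb)

  zero_dry <- n_dry == 0L
  if (any(zero_dry)) {
    warn(sprintf("%d block(s) have no dry land; area fraction set to 0",
                 sum(zero_dry)))
  }
  cs2 <- zone$grid$cellsize^2
  tibble(
    block_id = blocks$block_id, county_id = blocks$county_id,
    dry_area_m2 = n_dry * cs2, area_in_zone_m2 = n_zone * cs2,
    n_buildings = n_bld, buildings_in_zone = n_bld_in,
    fraction_area = ifelse(zero_dry, 0, n_zone / pmax(n_dry, 1L)),
    fraction_buildings = ifelse(n_bld > 0, n_bld_in / pmax(n_bld, 1L), NA_real_),
    zero_dry = zero_dry)
}

check_blocks_on_grid <- function(blocks, g) {
  x1 <- g$origin[1]; y1 <- g$origin[2]
  x2 <- x1 + g$nx * g$cellsize; y2 <- y1 + g$ny * g$cellsize
  off <- blocks$xmax <= x1 | blocks$xmin >= x2 |
    blocks$ymax <= y1 | blocks$ymin >= y2
  if (any(off)) {
    abort(sprintf(
      "coordinate mismatch: %d block(s) lie entirely outside the zone grid",
      sum(off)))
  }
  invisible(TRUE)
}

#' Estimate the population of a hazard zone from block counts
#'
#' Dasymetric interpolation of block population counts into the zone under
#' one of two assumptions: `uniform` (the in-zone share of a block's
#' population equals the in-zone share of its dry land) or `building` (it
#' equals the in-zone share of its buildings). Under `building`, a partially
#' overlapped block with no buildings falls back to its area fraction and is
#' flagged. Subgroup populations use the same per-block fraction as the
#' total, the block being the finest resolution at which composition is
#' known. Estimates are kept as reals; round only at report time.
#'
#' @inheritParams block_zone_fractions
#' @param method `"uniform"` or `"building"`.
#' @return an object of class `zone_estimate`: list with `blocks` (per-block
#'   fractions and estimates), `totals` (per county and for the region),
#'   `method`, and the zone's metadata.
#' @export
estimate_zone_population <- function(blocks, zone, buildings,
                                     method = c("uniform", "building"),
                                     water_mask) {
  method <- match.arg(method)
  if (nrow(blocks) == 0L) abort("no blocks supplied")
  if (length(unique(blocks$census_year %||% 1L)) > 1L) {
    abort("blocks must belong to a single census year")
  }
  fr <- block_zone_fractions(blocks, zone, buildings, water_mask)
  if (method == "uniform") {
    f <- fr$fraction_area
    fallback <- rep(FALSE, nrow(fr))
  } else {
    fallback <- fr$n_buildings == 0L & fr$fraction_area > 0 & fr$fraction_area < 1
    f <- ifelse(fr$n_buildings > 0L, fr$fraction_buildings, fr$fraction_area)
  }
  est <- fr
  est$fraction_used <- f
  est$fallback_uniform <- fallback
  est$pop_total <- blocks$pop_total
  est$pop_black <- blocks$pop_black
  est$pop_hispanic <- blocks$pop_hispanic
  est$est_total <- blocks$pop_total * f
  est$est_black <- blocks$pop_black * f
  est$est_hispanic <- blocks$pop_hispanic * f

  by_county <- est |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(dplyr::across(c("est_total", "est_black", "est_hispanic"), sum),
                     .groups = "drop") |>
    dplyr::mutate(scope = "county", .before = 1)
  region <- tibble(scope = "region", county_id = NA_character_,
                   est_total = sum(est$est_total),
                   est_black = sum(est$est_black),
                   est_hispanic = sum(est$est_hispanic))
  structure(list(
    blocks = est,
    totals = dplyr::bind_rows(by_county, region),
    method = method,
    zone_type = zone$zone_type, threshold_z_m = zone$threshold_z_m,
    sea_level_year = zone$sea_level_year
  ), class = "zone_estimate")
}

#' @export
print.zone_estimate <- function(x, ...) {
  tot <- x$totals[x$totals$scope == "region", ]
  cat(sprintf("<zone_estimate %s: total %.1f (black %.1f, hispanic %.1f), %d blocks>\n",
              x$method, tot$est_total, tot$est_black, tot$est_hispanic,
              nrow(x$blocks)))
  invisible(x)
}

#' Diagnostic census of partially vulnerable blocks
#'
#' Tallies the population of blocks entirely inside the zone and of blocks
#' with at least `min_fraction` (default 0.5%) of their dry land inside it —
#' the bracketing counts between which any interpolated estimate must fall.
#'
#' @inheritParams block_zone_fractions
#' @param min_fraction minimum dry-land fraction for the "all or part"
#'   class.
#' @return tibble with one row per class (`entirely_in_zone`,
#'   `all_or_part_in_zone`): block counts and population totals.
#' @export
partially_vulnerable_census <- function(blocks, zone, buildings, water_mask,
                                        min_fraction = 0.005) {
  fr <- block_zone_fractions(blocks, zone, buildings, water_mask)
  entirely <- fr$fraction_area == 1 & !fr$zero_dry
  any_part <- fr$fraction_area >= min_fraction
  mk <- function(sel, label) tibble(
    class = label, n_blocks = sum(sel),
    pop_total = sum(blocks$pop_total[sel]),
    pop_black = sum(blocks$pop_black[sel]),
    pop_hispanic = sum(blocks$pop_hispanic[sel]))
  dplyr::bind_rows(mk(entirely, "entirely_in_zone"),
                   mk(any_part, "all_or_part_in_zone"))
}
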