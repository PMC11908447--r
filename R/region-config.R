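#' Configuration for a synthetic coastal region
#'
#' Defines every parameter of the synthetic-region generator: geometry,
#' terrain, tides and sea-level rise, building placement, demographic mix,
#' and the between-census dynamics (emigration, growth, block subdivision).
#' The generated region carries person-level ground truth, so downstream
#' estimators can be scored against exact point-in-zone counts.
#'
#' Counties are rectangles laid side by side along the x axis with a shared
#' shoreline at y = 0; ground elevation rises inland (northward) as a tilted
#' plane plus smooth, seeded sinusoidal relief, so the low coastal fringe is
#' contiguous and strip areas below a contour have a closed form when
#' `noise_amp_m = 0`.
#'
#' @param seed integer; the only source of randomness. All operations derive
#'   deterministic sub-seeds from it.
#' @param n_counties,blocks_per_county region size. Blocks are produced by
#'   recursive guillotine splits of the county rectangle, giving an uneven,
#'   census-like mix of block sizes.
#' @param persons_per_county,buildings_per_county ground-truth totals per
#'   county. Each building is one housing unit; persons are allocated to
#'   buildings multinomially, so persons and units are proportional on
#'   average (about 2.5 persons per unit at the defaults).
#' @param county_size_km numeric length-2, county width (alongshore) and
#'   height (inland) in km.
#' @param cellsize_m raster cell size in meters for all grids.
#' @param terrain list: `slope_m_per_km` (inland rise of the base plane),
#'   `noise_amp_m` (amplitude of the smooth relief), `base_offset_m`
#'   (plane elevation at the shoreline; negative values put the fringe
#'   under water).
#' @param tidal_offset_m height of the tidal datum (mean higher high water,
#'   epoch midpoint 1992) above the fixed vertical datum of the elevation
#'   grid; subtracted to express elevations relative to sea level.
#' @param rise_rate_mm_per_yr sea-level rise rate; a single number for a
#'   constant surface, or a tibble of gauges (`x`, `y`, `rate_mm_yr`) to be
#'   interpolated by inverse distance.
#' @param census_years strictly increasing integer years; at least two.
#' @param placement_bias in \[0, 1\]: probability that a building is placed
#'   only on dry cells at or above its block's median dry-land elevation
#'   (people tend to build on the high part of their lots); 0 gives uniform
#'   placement over dry land.
#' @param person_mode `"buildings"` places persons exactly at building
#'   centroids (the building-based estimator's generative model);
#'   `"uniform"` scatters persons uniformly over block dry land (the
#'   adversarial mode matching the uniform-density assumption).
#' @param subgroup_mix list: `p_black`, `p_hispanic` per-county proportions
#'   (recycled), and `elev_gradient` (per-meter log-odds increase of the
#'   Black share as elevation falls below the county building mean;
#'   emulates minority concentration on low ground).
#' @param migration list of per-decade dynamics: `rate` (baseline emigration
#'   probability for persons below `elev_threshold_m` of sea-level-relative
#'   elevation), `county_multiplier` (per-county factors, recycled),
#'   `subgroup_multiplier` (named factors for `black`, `hispanic`),
#'   `growth_rate` (per-decade proportional in-migration, placed at random
#'   buildings at any elevation).
#' @param split_prob probability that a block is subdivided between
#'   consecutive censuses (an undeveloped part is carved off, leaving all
#'   buildings and persons in the developed part, as census remapping
#'   typically does).
#' @return a validated list of class `region_config`.
#' @export
region_config <- function(
    seed = 1L,
    n_counties = 2L,
    blocks_per_county = 100L,
    persons_per_county = 2500L,
    buildings_per_county = 1000L,
    county_size_km = c(4, 6),
    cellsize_m = 20,
    terrain = list(slope_m_per_km = 1.5, noise_amp_m = 0.25, base_offset_m = -0.5),
    tidal_offset_m = 0.15,
    rise_rate_mm_per_yr = 4,
    census_years = c(1990L, 2000L, 2010L, 2020L),
    placement_bias = 0.7,
    person_mode = c("buildings", "uniform"),
    subgroup_mix = list(p_black = c(0.30, 0.10, 0.20, 0.15),
                        p_hispanic = c(0.10, 0.20, 0.12, 0.08),
                        elev_gradient = 0.4),
    migration = list(rate = 0.05, elev_threshold_m = 1,
                     county_multiplier = 1,
                     subgroup_multiplier = c(black = 1.5, hispanic = 1),
                     growth_rate = 0.02),
    split_prob = 0.05) {
  person_mode <- match.arg(person_mode)
  cfg <- list(
    seed = as.integer(seed), n_counties = as.integer(n_counties),
    blocks_per_county = as.integer(blocks_per_county),
    persons_per_county = as.integer(persons_per_county),
    buildings_per_county = as.integer(buildings_per_county),
    county_size_km = as.numeric(county_size_km), cellsize_m = cellsize_m,
    terrain = terrain, tidal_offset_m = tidal_offset_m,
    rise_rate_mm_per_yr = rise_rate_mm_per_yr,
    census_years = as.integer(census_years),
    placement_bias = placement_bias, person_mode = person_mode,
    subgroup_mix = subgroup_mix, migration = migration,
    split_prob = split_prob)
  validate_region_config(cfg)
  structure(cfg, class = "region_config")
}

validate_region_config <- function(cfg) {
  stopifnot_scalar_number(cfg$seed, "seed")
  if (cfg$n_counties < 1L) abort("need at least one county")
  if (cfg$blocks_per_county < 1L) abort("need at least one block per county")
  if (length(cfg$county_size_km) != 2L || any(cfg$county_size_km <= 0)) {
    abort("degenerate geometry: county dimensions must be positive")
  }
  if (length(cfg$census_years) < 2L) {
    abort("unsupported census_years: at least two census years are required")
  }
  if (any(diff(cfg$census_years) <= 0)) {
    abort("census_years must be strictly increasing")
  }
  stopifnot_scalar_number(cfg$placement_bias, "placement_bias", 0, 1)
  stopifnot_scalar_number(cfg$split_prob, "split_prob", 0, 1)
  pb <- rep_len(cfg$subgroup_mix$p_black, cfg$n_counties)
  ph <- rep_len(cfg$subgroup_mix$p_hispanic, cfg$n_counties)
  if (any(pb < 0 | pb > 1 | ph < 0 | ph > 1) || any(pb + ph > 1)) {
    abort("subgroup proportions must lie in [0,1] and sum to at most 1 per county")
  }
  mig <- cfg$migration
  stopifnot_scalar_number(mig$rate %||% 0, "migration$rate", 0, 1)
  stopifnot_scalar_number(mig$growth_rate %||% 0, "migration$growth_rate", 0, 1)
  invisible(cfg)
}
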