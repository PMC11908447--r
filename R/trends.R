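#' Zone-population totals over census years and sea-level years
#'
#' Crosses every census year with every sea-level year: the cell
#' (census year c, sea-level year s) holds the interpolated population of
#' the census of year c living inside the hazard zone delineated for the
#' sea level of year s. The diagonal is the actual series; fixing the
#' sea-level year at the terminal year isolates demographic change; fixing
#' the census isolates the effect of rising sea level.
#'
#' @param blocks_by_year block table covering all census years (column
#'   `census_year`).
#' @param zones named list of `hazard_zone` objects keyed by sea-level year
#'   (all with the same threshold).
#' @param buildings,water_mask as in [estimate_zone_population()].
#' @param method interpolation method, `"uniform"` or `"building"`.
#' @return object of class `decomp_series`: a 3-d array
#'   `[census year, sea-level year, subgroup]` with subgroups `total`,
#'   `black`, `hispanic`, plus `census_years` and `sea_level_years`.
#' @export
zone_population_series <- function(blocks_by_year, zones, buildings,
                                   water_mask,
                                   method = c("uniform", "building")) {
  method <- match.arg(method)
  cyears <- sort(unique(blocks_by_year$census_year))
  zyears <- suppressWarnings(as.integer(names(zones)))
  if (length(zyears) != length(zones) || anyNA(zyears)) {
    abort("`zones` must be a list named by sea-level year")
  }
  zs <- vapply(zones, `[[`, 0, "threshold_z_m")
  if (length(unique(zs)) > 1L) abort("all zones must share one threshold z")
  arr <- array(NA_real_, dim = c(length(cyears), length(zyears), 3),
               dimnames = list(census = cyears, sea_level = zyears,
                               subgroup = c("total", "black", "hispanic")))
  for (ci in seq_along(cyears)) {
    blk <- blocks_by_year[blocks_by_year$census_year == cyears[ci], ]
    if (nrow(blk) == 0L) abort(sprintf("census year %d missing", cyears[ci]))
    for (zi in seq_along(zyears)) {
      est <- estimate_zone_population(blk, zones[[zi]], buildings,
                                      method = method,
                                      water_mask = water_mask)
      tot <- est$totals[est$totals$scope == "region", ]
      arr[ci, zi, ] <- c(tot$est_total, tot$est_black, tot$est_hispanic)
    }
  }
  structure(list(values = arr, census_years = cyears,
                 sea_level_years = zyears, method = method,
                 threshold_z_m = zs[[1]]),
            class = "decomp_series")
}

#' Build a decomposition series from a plain matrix
#'
#' For accounting checks and externally supplied totals: wraps a matrix of
#' zone-population totals (rows = census years, columns = sea-level years)
#' as a `decomp_series`.
#'
#' @param m numeric matrix with dimnames giving census years (rows) and
#'   sea-level years (columns).
#' @param subgroup label stored for the single subgroup slice.
#' @return a `decomp_series`.
#' @export
as_decomp_series <- function(m, subgroup = "total") {
  cy <- as.integer(rownames(m)); zy <- as.integer(colnames(m))
  if (anyNA(cy) || anyNA(zy)) abort("matrix must have year dimnames")
  arr <- array(NA_real_, dim = c(length(cy), length(zy), 3),
               dimnames = list(census = cy, sea_level = zy,
                               subgroup = c("total", "black", "hispanic")))
  arr[, , subgroup] <- m
  structure(list(values = arr, census_years = cy, sea_level_years = zy,
                 method = "external", threshold_z_m = NA_real_),
            class = "decomp_series")
}

#' Decompose zone-population change into demographic and sea-level parts
#'
#' Both components are anchored at the terminal year: the demographic
#' component holds the zone at the terminal sea level and changes the
#' census (`cell(y1, y1) - cell(y0, y1)`); the sea-level component holds
#' the census at the terminal year and changes the zone
#' (`cell(y1, y1) - cell(y1, y0)`). The actual change is the diagonal
#' difference, and the cross-term `actual - d_census - d_sea_level` is
#' reported explicitly rather than silently absorbed.
#'
#' @param series a `decomp_series`.
#' @param y0,y1 start and end years (both must appear among the census and
#'   the sea-level years).
#' @param subgroup one of `"total"`, `"black"`, `"hispanic"`.
#' @return list with `d_census`, `d_sea_level`, `actual`, `cross_term`.
#' @export
decompose_change <- function(series, y0, y1, subgroup = "total") {
  if (y0 > y1) abort("y0 must not exceed y1")
  v <- series$values[, , subgroup, drop = TRUE]
  if (length(dim(v)) != 2L) v <- matrix(v, length(series$census_years),
                                        length(series$sea_level_years))
  ci <- match(c(y0, y1), series$census_years)
  zi <- match(c(y0, y1), series$sea_level_years)
  if (anyNA(ci) || anyNA(zi)) abort("y0 and y1 must be present in the series")
  c00 <- v[ci[1], zi[1]]; c01 <- v[ci[1], zi[2]]
  c10 <- v[ci[2], zi[1]]; c11 <- v[ci[2], zi[2]]
  d_census <- c11 - c01
  d_sea <- c11 - c10
  actual <- c11 - c00
  list(d_census = d_census, d_sea_level = d_sea, actual = actual,
       cross_term = actual - d_census - d_sea)
}

#' Sum per-county decadal changes into 30-year totals and a national figure
#'
#' The accounting layer shared by [county_apparent_migration()] and direct
#' use on published tables: per-county decadal changes in zone population
#' (all against one fixed zone) are summed to period totals, and the
#' national apparent-emigration figure is the sum of period changes over
#' the counties where that change is negative.
#'
#' @param decadal tibble with columns `county_id`, `decade` (any ordered
#'   label), and one or more numeric change columns (e.g. `change_total`,
#'   `change_black`).
#' @return list with `by_county` (per-county period totals) and `national`
#'   (named vector: for each change column, the sum over counties with a
#'   negative period total; 0 if none).
#' @export
emigration_accounting <- function(decadal) {
  chg_cols <- setdiff(names(decadal), c("county_id", "decade"))
  chg_cols <- chg_cols[vapply(decadal[chg_cols], is.numeric, TRUE)]
  if (!length(chg_cols)) abort("no numeric change columns found")
  by_county <- decadal |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(chg_cols), sum),
                     .groups = "drop")
  national <- vapply(chg_cols, function(cl) {
    x <- by_county[[cl]]
    s <- sum(x[x < 0])
    if (length(x[x < 0])) s else 0
  }, 0)
  list(by_county = by_county, national = national)
}

#' Apparent migration from a hazard zone, by county
#'
#' Computes, per county, the decadal and full-period changes in the
#' population living inside one fixed hazard zone (the terminal-year sea
#' level), expresses the period change as a percent of the county's
#' base-year population (total and per subgroup), and flags counties where
#' apparent emigration exceeds `threshold_pct` of county population. A
#' population decline is only "apparent" emigration: deaths exceeding
#' births are indistinguishable from moves.
#'
#' @param zone_pop tibble of zone populations per county and census year:
#'   columns `county_id`, `census_year`, `pop_total`, `pop_black`,
#'   `pop_hispanic` (one fixed zone throughout).
#' @param county_pop same columns for the whole county (denominators).
#' @param threshold_pct inclusion flag threshold, percent of county
#'   base-year population (default 1).
#' @return list of class `emigration_table`: `by_decade` (county x decade
#'   changes), `by_county` (period change, percents, flag), `national`
#'   (apparent-emigration totals per subgroup, each summed over counties
#'   where that subgroup's change is negative).
#' @export
county_apparent_migration <- function(zone_pop, county_pop,
                                      threshold_pct = 1) {
  yrs <- sort(unique(zone_pop$census_year))
  if (length(yrs) < 2L) abort("need at least two census years")
  complete <- zone_pop |>
    dplyr::count(.data$county_id) |>
    dplyr::filter(.data$n == length(yrs))
  dropped <- setdiff(unique(zone_pop$county_id), complete$county_id)
  if (length(dropped)) {
    warn(sprintf("excluding %d county(ies) missing a census year: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
    zone_pop <- zone_pop[zone_pop$county_id %in% complete$county_id, ]
  }
  by_decade <- zone_pop |>
    dplyr::arrange(.data$county_id, .data$census_year) |>
    dplyr::group_by(.data$county_id) |>
    dplyr::reframe(decade = paste(yrs[-length(yrs)], yrs[-1], sep = "-"),
                   change_total = diff(.data$pop_total),
                   change_black = diff(.data$pop_black),
                   change_hispanic = diff(.data$pop_hispanic))
  acc <- emigration_accounting(by_decade)
  base <- county_pop[county_pop$census_year == yrs[1], ]
  by_county <- acc$by_county |>
    dplyr::left_join(base[, c("county_id", "pop_total", "pop_black",
                              "pop_hispanic")], by = "county_id") |>
    dplyr::mutate(
      pct_total = 100 * .data$change_total / .data$pop_total,
      pct_black = ifelse(.data$pop_black > 0,
                         100 * .data$change_black / .data$pop_black, NA_real_),
      pct_hispanic = ifelse(.data$pop_hispanic > 0,
                            100 * .data$change_hispanic / .data$pop_hispanic,
                            NA_real_),
      flagged = .data$change_total < 0 & abs(.data$pct_total) >= threshold_pct)
  structure(list(by_decade = by_decade, by_county = by_county,
                 national = acc$national, base_year = yrs[1],
                 end_year = yrs[length(yrs)]),
            class = "emigration_table")
}

#' @export
print.emigration_table <- function(x, ...) {
  cat(sprintf("<emigration_table %d-%d: national apparent emigration %s>\n",
              x$base_year, x$end_year,
              paste(sprintf("%s %.0f", names(x$national), x$national),
                    collapse = ", ")))
  print(x$by_county)
  invisible(x)
}

#' Per-county zone populations for every census year
#'
#' Convenience wrapper running [estimate_zone_population()] for each census
#' year against one fixed zone and returning tidy per-county totals, the
#' input expected by [county_apparent_migration()].
#'
#' @inheritParams zone_population_series
#' @param zone a single `hazard_zone` (held fixed across years).
#' @return tibble `county_id`, `census_year`, `pop_total`, `pop_black`,
#'   `pop_hispanic`.
#' @export
county_zone_populations <- function(blocks_by_year, zone, buildings,
                                    water_mask,
                                    method = c("uniform", "building")) {
  method <- match.arg(method)
  yrs <- sort(unique(blocks_by_year$census_year))
  dplyr::bind_rows(lapply(yrs, function(yy) {
    blk <- blocks_by_year[blocks_by_year$census_year == yy, ]
    est <- estimate_zone_population(blk, zone, buildings, method = method,
                                    water_mask = water_mask)
    ct <- est$totals[est$totals$scope == "county", ]
    tibble(county_id = ct$county_id, census_year = yy,
           pop_total = ct$est_total, pop_black = ct$est_black,
           pop_hispanic = ct$est_hispanic)
  }))
}
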