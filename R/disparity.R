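#' Nationwide ratio of disproportionality
#'
#' The subgroup's share of the hazard-zone population divided by its share
#' of the reference population: a value of 1.63 means members of the
#' subgroup are 63% more likely than the general population to live in the
#' zone.
#'
#' @param zone_pop named numeric vector of zone populations with at least
#'   `total` and the subgroup entry (e.g. `c(total = ..., black = ...)`).
#' @param ref_pop named numeric vector of reference (national or county)
#'   populations, same names.
#' @param subgroup name of the subgroup entry.
#' @return the ratio (scalar). Errors if the reference subgroup population
#'   is zero.
#' @export
nationwide_disproportionality <- function(zone_pop, ref_pop,
                                          subgroup = "black") {
  if (ref_pop[["total"]] <= 0 || zone_pop[["total"]] <= 0) {
    abort("total populations must be positive")
  }
  if (ref_pop[[subgroup]] <= 0) {
    abort(sprintf("reference %s population is zero; ratio undefined", subgroup))
  }
  (zone_pop[[subgroup]] / zone_pop[["total"]]) /
    (ref_pop[[subgroup]] / ref_pop[["total"]])
}

#' County-weighted ratio of disproportionality
#'
#' Filters out the effect of subgroup composition differing across
#' counties: the observed national subgroup total inside the zone divided
#' by what that total would be if, within every county, subgroup presence
#' in the zone were proportional to the subgroup's share of the county.
#' Equivalently an inverse weighted average of county-specific
#' disproportionality ratios. Counties with no zone population contribute
#' zero to both sums; counties wholly outside the zone still shape the
#' expected total through their zero zone population.
#'
#' @param county_table tibble with per-county columns `zone_subgroup`
#'   (subgroup population in the zone), `zone_total`, `county_subgroup`,
#'   `county_total`.
#' @return the ratio (scalar). Errors if the expected total is zero.
#' @export
county_weighted_disproportionality <- function(county_table) {
  ct <- county_table
  if (any(ct$county_total <= 0)) abort("county totals must be positive")
  expected <- sum(ct$zone_total * ct$county_subgroup / ct$county_total)
  if (expected <= 0) {
    abort("expected subgroup zone population is zero; ratio undefined")
  }
  sum(ct$zone_subgroup) / expected
}

#' Disparity in emigration from hazard zones
#'
#' Given per-county apparent-emigration magnitudes from a zone and
#' base-year populations, computes the subgroup's share of emigration, its
#' share of the base-year population, the nationwide disproportionality
#' ratio of the two, and the county-weighted analogue built from the same
#' expected-counts construction (expected subgroup emigration in a county
#' is total county emigration times the subgroup's base-year county
#' share).
#'
#' @param county_emig tibble with `county_id`, `emig_total`,
#'   `emig_subgroup` — apparent-emigration magnitudes (non-negative) per
#'   county.
#' @param county_base tibble with `county_id`, `pop_total`, `pop_subgroup`
#'   — base-year county populations.
#' @return list of class `disparity_metrics`: `share_emigration`,
#'   `share_population`, `nationwide_ratio`, `county_weighted_ratio`.
#' @export
emigration_disparity <- function(county_emig, county_base) {
  m <- dplyr::inner_join(county_emig, county_base, by = "county_id")
  tot_e <- sum(m$emig_total)
  if (tot_e <= 0) abort("zero total emigration; shares undefined")
  share_e <- sum(m$emig_subgroup) / tot_e
  share_p <- sum(m$pop_subgroup) / sum(m$pop_total)
  expected <- sum(m$emig_total * m$pop_subgroup / m$pop_total)
  structure(list(
    share_emigration = share_e,
    share_population = share_p,
    nationwide_ratio = share_e / share_p,
    county_weighted_ratio = if (expected > 0) sum(m$emig_subgroup) / expected
                            else NA_real_
  ), class = "disparity_metrics")
}

#' @export
print.disparity_metrics <- function(x, ...) {
  cat(sprintf(
    "<disparity: emigration share %.3f vs population share %.3f; nationwide %.2f, county-weighted %.2f>\n",
    x$share_emigration, x$share_population, x$nationwide_ratio,
    x$county_weighted_ratio))
  invisible(x)
}

#' Disparity of hazard-zone exposure across a categorical overlay
#'
#' Overlays categorical polygons (e.g. historical mortgage-risk grades) on
#' the blocks and, for each category, interpolates its population and the
#' part of that population inside the hazard zone; the zone-share ratio
#' compares each category's in-zone share to the overall in-zone share. A
#' ratio of 1.6 for a category means its residents are 60% more likely than
#' the general population to live in the zone.
#'
#' @param zone a `hazard_zone`.
#' @param overlay tibble of rectangles with `category`, `xmin`, `xmax`,
#'   `ymin`, `ymax`; categories must not overlap.
#' @param blocks,buildings,water_mask as in [estimate_zone_population()].
#' @param method interpolation method.
#' @return tibble per category: `population`, `population_in_zone`,
#'   `zone_share`, `ratio_vs_overall`.
#' @export
overlay_disparity <- function(zone, overlay, blocks, buildings, water_mask,
                              method = c("uniform", "building")) {
  method <- match.arg(method)
  cats <- unique(overlay$category)
  cat_masks <- lapply(cats, function(cg) {
    sel <- overlay[overlay$category == cg, ]
    Reduce(`|`, lapply(seq_len(nrow(sel)), function(i) {
      rect_cell_mask(zone$grid, sel$xmin[i], sel$xmax[i],
                     sel$ymin[i], sel$ymax[i])
    }))
  })
  if (length(cats) > 1L) {
    overlap <- Reduce(`+`, lapply(cat_masks, function(m) m * 1L))
    if (any(overlap > 1L)) abort("overlay categories overlap")
  }
  overall <- estimate_zone_population(blocks, zone, buildings,
                                      method = method,
                                      water_mask = water_mask)
  tot_all <- sum(blocks$pop_total)
  zone_all <- overall$totals$est_total[overall$totals$scope == "region"]
  overall_share <- zone_all / tot_all
  dplyr::bind_rows(lapply(seq_along(cats), function(k) {
    zc <- new_hazard_zone(cat_masks[[k]], zone$grid, zone_type = "overlay")
    zcz <- new_hazard_zone(cat_masks[[k]] & zone$mask, zone$grid,
                           zone_type = "overlay")
    pop_c <- estimate_zone_population(blocks, zc, buildings, method = method,
                                      water_mask = water_mask)
    pop_cz <- estimate_zone_population(blocks, zcz, buildings,
                                       method = method,
                                       water_mask = water_mask)
    p <- pop_c$totals$est_total[pop_c$totals$scope == "region"]
    pz <- pop_cz$totals$est_total[pop_cz$totals$scope == "region"]
    tibble(category = cats[k], population = p, population_in_zone = pz,
           zone_share = if (p > 0) pz / p else NA_real_,
           ratio_vs_overall = if (p > 0) (pz / p) / overall_share else NA_real_)
  }))
}
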