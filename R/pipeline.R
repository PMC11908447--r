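#' Run the full exposure-analysis pipeline on a synthetic region
#'
#' Orchestrates every stage end to end: region generation, year-specific
#' hazard-zone delineation, dasymetric population estimates under both
#' density assumptions, the census-year x sea-level-year decomposition
#' series, county apparent-migration accounting, residence and emigration
#' disparity ratios, and (optionally) the stratified-sample ratio-estimator
#' validation. All outputs are written as CSV (plus GeoJSON/ASCII layers
#' for the region itself) under `out_dir`, together with a manifest holding
#' the configuration hash and seed; a rerun with the same configuration is
#' bit-identical.
#'
#' @param config a [region_config()].
#' @param out_dir output directory.
#' @param z_thresholds elevation thresholds (m) for the hazard zones.
#' @param methods interpolation methods to run.
#' @param validate if `TRUE`, run the stratified-sample validation against
#'   ground truth for the first threshold and write a CV report.
#' @param strata the [strata_rules()] used when `validate = TRUE`.
#' @param sample_frac fraction of each stratum drawn in validation.
#' @param write_layers if `TRUE` (default) also write the region layers.
#' @return invisibly, a list with the bundle and every computed table.
#' @export
run_pipeline <- function(config, out_dir,
                         z_thresholds = c(1, 3),
                         methods = c("uniform", "building"),
                         validate = TRUE,
                         strata = strata_rules(density_breaks = c(0.3, 1)),
                         sample_frac = 0.3,
                         write_layers = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- generate_region(config)
  if (write_layers) write_region_bundle(bundle, file.path(out_dir, "region"))

  years <- config$census_years
  terminal <- max(years)
  rel_by_year <- lapply(years, function(yy) {
    relative_elevation_grid(bundle$elev, bundle$tidal, bundle$rate, yy)
  })
  names(rel_by_year) <- years

  results <- list(bundle = bundle)
  est_rows <- list()
  for (z in z_thresholds) {
    zones <- lapply(rel_by_year, delineate_low_land, z = z,
                    water_mask = bundle$water)
    zone_term <- zones[[as.character(terminal)]]
    for (m in methods) {
      series <- zone_population_series(bundle$blocks, zones,
                                       bundle$buildings, bundle$water,
                                       method = m)
      dec <- decompose_change(series, min(years), terminal)
      cty <- county_zone_populations(bundle$blocks, zone_term,
                                     bundle$buildings, bundle$water,
                                     method = m)
      emig <- county_apparent_migration(cty, county_population_table(bundle))
      est_rows[[paste(z, m)]] <- tibble(
        z = z, method = m,
        est_total = series$values[as.character(terminal),
                                  as.character(terminal), "total"],
        est_black = series$values[as.character(terminal),
                                  as.character(terminal), "black"],
        d_census = dec$d_census, d_sea_level = dec$d_sea_level,
        actual = dec$actual, cross_term = dec$cross_term,
        national_emigration = emig$national[["change_total"]])
      results[[sprintf("series_z%g_%s", z, m)]] <- series
      results[[sprintf("emigration_z%g_%s", z, m)]] <- emig
      utils::write.csv(
        series_to_table(series),
        file.path(out_dir, sprintf("series_z%g_%s.csv", z, m)),
        row.names = FALSE)
      utils::write.csv(
        emig$by_county,
        file.path(out_dir, sprintf("emigration_z%g_%s.csv", z, m)),
        row.names = FALSE)
    }
    # residence disparity at the terminal census for this zone
    disp <- residence_disparity_table(bundle, zone_term, terminal)
    results[[sprintf("disparity_z%g", z)]] <- disp
    utils::write.csv(disp, file.path(out_dir, sprintf("disparity_z%g.csv", z)),
                     row.names = FALSE)
  }
  summary_tbl <- dplyr::bind_rows(est_rows)
  utils::write.csv(summary_tbl, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  results$summary <- summary_tbl

  if (validate) {
    val <- validate_with_sample(bundle, z = z_thresholds[1],
                                rules = strata, sample_frac = sample_frac,
                                seed = config$seed)
    results$validation <- val
    utils::write.csv(val$report, file.path(out_dir, "validation_cv.csv"),
                     row.names = FALSE)
  }
  write_manifest(config, file.path(out_dir, "manifest.txt"),
                 extra = list(z_thresholds = paste(z_thresholds, collapse = ","),
                              methods = paste(methods, collapse = ",")))
  invisible(results)
}

# Whole-county populations per census year, from the block tables.
county_population_table <- function(bundle) {
  bundle$blocks |>
    dplyr::group_by(.data$county_id, .data$census_year) |>
    dplyr::summarise(pop_total = sum(.data$pop_total),
                     pop_black = sum(.data$pop_black),
                     pop_hispanic = sum(.data$pop_hispanic),
                     .groups = "drop")
}

series_to_table <- function(series) {
  df <- as.data.frame.table(series$values, responseName = "population")
  names(df)[1:3] <- c("census_year", "sea_level_year", "subgroup")
  as_tibble(df)
}

residence_disparity_table <- function(bundle, zone, year) {
  blk <- bundle$blocks[bundle$blocks$census_year == year, ]
  est <- estimate_zone_population(blk, zone, bundle$buildings,
                                  method = "building",
                                  water_mask = bundle$water)
  ct <- est$totals[est$totals$scope == "county", ]
  cpop <- county_population_table(bundle)
  cpop <- cpop[cpop$census_year == year, ]
  m <- dplyr::inner_join(ct, cpop, by = "county_id")
  reg <- est$totals[est$totals$scope == "region", ]
  dplyr::bind_rows(lapply(c("black", "hispanic"), function(sg) {
    zc <- m[[paste0("est_", sg)]]; cc <- m[[paste0("pop_", sg)]]
    tibble(
      subgroup = sg, census_year = year,
      nationwide_ratio = nationwide_disproportionality(
        c(total = reg$est_total, x = reg[[paste0("est_", sg)]]),
        c(total = sum(cpop$pop_total), x = sum(cpop[[paste0("pop_", sg)]])),
        subgroup = "x"),
      county_weighted_ratio = county_weighted_disproportionality(
        tibble(zone_subgroup = zc, zone_total = m$est_total,
               county_subgroup = cc, county_total = m$pop_total)))
  }))
}

# Stratified-sample validation of both interpolation methods against the
# synthetic ground truth (true person counts per block in the zone).
validate_with_sample <- function(bundle, z, rules, sample_frac, seed) {
  year <- min(bundle$config$census_years)
  rel <- relative_elevation_grid(bundle$elev, bundle$tidal, bundle$rate, year)
  zone <- delineate_low_land(rel, z, bundle$water)
  blk <- bundle$blocks[bundle$blocks$census_year == year, ]
  fr <- block_zone_fractions(blk, zone, bundle$buildings, bundle$water)
  truth <- true_zone_counts(bundle, zone, year)
  strata <- stratify_blocks(blk, fr, rules)
  N_h <- attr(strata, "sizes")
  sizes <- setNames(pmin(N_h, pmax(2L, ceiling(sample_frac * N_h))),
                    names(N_h))
  samp <- draw_sample(strata, sizes, seed)
  ests <- lapply(c(uniform = "uniform", building = "building"), function(m) {
    est <- estimate_zone_population(blk, zone, bundle$buildings, method = m,
                                    water_mask = bundle$water)
    eb <- est$blocks
    s <- samp
    s$y <- truth$true_in_zone[match(s$block_id, truth$block_id)]
    s$x <- eb$est_total[match(s$block_id, eb$block_id)]
    frame_total <- sum(eb$est_total[eb$block_id %in% strata$block_id])
    combined_ratio_estimate(s, N_h = N_h[names(sizes)],
                            x_total = frame_total)
  })
  list(estimates = ests, report = cv_report(ests), strata = strata)
}

#' True person counts inside a zone, per block
#'
#' Ground-truth oracle for synthetic regions: counts the persons of one
#' census year whose location falls in a zone cell, per block.
#'
#' @param bundle a `region_bundle`.
#' @param zone a `hazard_zone`.
#' @param year census year.
#' @return tibble `block_id`, `true_in_zone`, `true_black_in_zone`,
#'   `true_hispanic_in_zone`.
#' @export
true_zone_counts <- function(bundle, zone, year) {
  p <- bundle$persons[bundle$persons$census_year == year, ]
  in_zone <- zone$mask[p$cell]
  blk <- bundle$blocks[bundle$blocks$census_year == year, ]
  pid <- assign_blocks(p$x, p$y, blk)
  lv <- blk$block_id
  tibble(
    block_id = lv,
    true_in_zone = as.integer(table(factor(pid[in_zone], levels = lv))),
    true_black_in_zone = as.integer(table(factor(
      pid[in_zone & p$subgroup == "black"], levels = lv))),
    true_hispanic_in_zone = as.integer(table(factor(
      pid[in_zone & p$subgroup == "hispanic"], levels = lv))))
}
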