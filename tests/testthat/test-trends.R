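test_that("the census x sea-level matrix agrees with direct zone estimates", {
  b <- small_bundle()
  zones <- list(`1990` = zone_at(b, 1, 1990), `2000` = zone_at(b, 1, 2000))
  series <- suppressWarnings(
    zone_population_series(b$blocks, zones, b$buildings, b$water,
                           method = "building"))
  for (cy in c(1990, 2000)) {
    for (zy in c(1990, 2000)) {
      est <- suppressWarnings(
        estimate_zone_population(blocks_of_year(b, cy),
                                 zones[[as.character(zy)]],
                                 b$buildings, "building", b$water))
      expect_equal(series$values[as.character(cy), as.character(zy), "total"],
                   region_total(est))
    }
  }
  expect_error(
    zone_population_series(b$blocks,
                           list(zone_at(b, 1, 1990)), b$buildings, b$water),
    "named")
})

test_that("without sea-level rise the sea-level dimension is degenerate", {
  cfg <- small_config(seed = 23L, rise_rate_mm_per_yr = 0)
  b <- generate_region(cfg)
  zones <- list(`1990` = zone_at(b, 1, 1990), `2000` = zone_at(b, 1, 2000))
  expect_identical(zones[["1990"]]$mask, zones[["2000"]]$mask)
  series <- suppressWarnings(
    zone_population_series(b$blocks, zones, b$buildings, b$water,
                           method = "uniform"))
  expect_equal(series$values[, "1990", ], series$values[, "2000", ])
  dec <- decompose_change(series, 1990, 2000)
  expect_equal(dec$d_sea_level, 0)
  expect_equal(dec$cross_term, 0)
  expect_equal(dec$actual, dec$d_census)
})

test_that("with a frozen population the census dimension is degenerate", {
  cfg <- small_config(seed = 24L, split_prob = 0,
                      migration = list(rate = 0, growth_rate = 0))
  b <- generate_region(cfg)
  zones <- list(`1990` = zone_at(b, 1, 1990), `2000` = zone_at(b, 1, 2000))
  series <- suppressWarnings(
    zone_population_series(b$blocks, zones, b$buildings, b$water,
                           method = "building"))
  expect_equal(series$values["1990", , ], series$values["2000", , ])
  dec <- decompose_change(series, 1990, 2000)
  expect_equal(dec$d_census, 0)
  expect_equal(dec$actual, dec$d_sea_level)
})

test_that("decomposition components always close against the explicit cross-term", {
  set.seed(8)
  m <- matrix(runif(4, 100, 1000), 2, 2,
              dimnames = list(c(1990, 2020), c(1990, 2020)))
  dec <- decompose_change(as_decomp_series(m), 1990, 2020)
  expect_equal(dec$d_census + dec$d_sea_level + dec$cross_term, dec$actual)
  expect_equal(dec$d_census, m[2, 2] - m[1, 2])
  expect_equal(dec$d_sea_level, m[2, 2] - m[2, 1])
  expect_equal(dec$actual, m[2, 2] - m[1, 1])
  # a degenerate interval changes nothing
  z <- decompose_change(as_decomp_series(m), 1990, 1990)
  expect_equal(unlist(z), c(d_census = 0, d_sea_level = 0, actual = 0,
                            cross_term = 0))
  expect_error(decompose_change(as_decomp_series(m), 1990, 2010), "present")
  expect_error(decompose_change(as_decomp_series(m), 2020, 1990), "exceed")
})

test_that("national apparent emigration sums only the counties that lost population", {
  decadal <- tibble::tibble(
    county_id = rep(c("A", "B", "C"), each = 2),
    decade = rep(c("d1", "d2"), 3),
    change_total = c(-100, -50, 200, -20, -5, 10),
    change_black = c(-60, -20, 10, -15, 2, 3))
  acc <- emigration_accounting(decadal)
  expect_equal(acc$by_county$change_total, c(-150, 180, 5))
  # A lost 150 and is the only total loser; for Black residents A and B lost
  expect_equal(unname(acc$national["change_total"]), -150)
  expect_equal(unname(acc$national["change_black"]), -80 - 5)
  up <- emigration_accounting(dplyr::mutate(decadal, change_total = abs(change_total),
                                            change_black = abs(change_black)))
  expect_equal(unname(up$national["change_total"]), 0)
  expect_error(emigration_accounting(decadal[, 1:2]), "no numeric change")
})

test_that("county migration tables report decadal diffs, percents, and flags", {
  zone_pop <- tibble::tibble(
    county_id = rep(c("A", "B"), each = 3),
    census_year = rep(c(1990, 2000, 2010), 2),
    pop_total = c(1000, 900, 850, 500, 505, 520),
    pop_black = c(400, 330, 310, 100, 104, 110),
    pop_hispanic = c(50, 48, 47, 30, 31, 33))
  county_pop <- tibble::tibble(
    county_id = c("A", "B"), census_year = 1990,
    pop_total = c(10000, 2000), pop_black = c(3000, 300),
    pop_hispanic = c(500, 100))
  et <- county_apparent_migration(zone_pop, county_pop, threshold_pct = 1)
  expect_equal(nrow(et$by_decade), 4L)
  expect_equal(et$by_decade$change_total[et$by_decade$county_id == "A"],
               c(-100, -50))
  a <- et$by_county[et$by_county$county_id == "A", ]
  expect_equal(a$change_total, -150)
  expect_equal(a$pct_total, 100 * -150 / 10000)
  expect_true(a$flagged)     # 1.5% of county population
  b <- et$by_county[et$by_county$county_id == "B", ]
  expect_false(b$flagged)    # B grew
  expect_equal(unname(et$national["change_total"]), -150)
  expect_equal(unname(et$national["change_black"]), -90)
  # decadal changes and period change are the same accounting
  expect_equal(sum(et$by_decade$change_total), sum(et$by_county$change_total))
  expect_warning(
    county_apparent_migration(zone_pop[-1, ], county_pop),
    "missing a census year")
})

test_that("apparent emigration from the low zone matches the generator's migration log", {
  # growth and remapping are switched off, so the only change in the
  # population below the migration threshold is the logged emigration
  cfg <- small_config(seed = 29L, split_prob = 0,
                      migration = list(rate = 0.2, elev_threshold_m = 1,
                                       growth_rate = 0,
                                       subgroup_multiplier = c(black = 1.5)))
  b <- generate_region(cfg)
  # the migration rule acts on elevation relative to the 1992 epoch datum
  zone <- zone_at(b, 1, 1992)
  truth <- lapply(cfg$census_years, function(yy) {
    tz <- true_zone_counts(b, zone, yy)
    blk <- blocks_of_year(b, yy)
    tibble::tibble(county_id = "C01", census_year = yy,
                   pop_total = sum(tz$true_in_zone),
                   pop_black = sum(tz$true_black_in_zone),
                   pop_hispanic = sum(tz$true_hispanic_in_zone))
  })
  truth <- dplyr::bind_rows(truth)
  log <- b$migration_log
  d_total <- diff(truth$pop_total)
  expect_equal(-d_total, log$removed[log$subgroup == "total"])
  expect_equal(-diff(truth$pop_black), log$removed[log$subgroup == "black"])
})
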