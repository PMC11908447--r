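# A hand-built scene: a 10 x 10 grid of 10 m cells, the hazard zone is the
# western strip x < 30, and three one-block cases cover the fully-inside,
# fully-outside, and straddling situations.
hand_scene <- function() {
  # zone = columns with center x < 30 (relative elevation 0 < z = 1)
  rel <- cp_grid(matrix(ifelse(row(matrix(0, 10, 10)) <= 3, 0, 5), 10, 10),
                 cellsize = 10)
  water <- matrix(FALSE, 10, 10)
  zone <- delineate_low_land(rel, 1, water)
  blocks <- tibble::tibble(
    block_id = c("in", "out", "half"),
    county_id = "C01",
    xmin = c(0, 50, 0), xmax = c(20, 100, 60),
    ymin = c(0, 0, 50), ymax = c(50, 50, 100),
    pop_total = c(40L, 60L, 100L), pop_black = c(10L, 20L, 30L),
    pop_hispanic = c(4L, 6L, 10L), census_year = 2020L,
    area_m2 = c(1000, 2500, 3000), housing_units = c(4L, 6L, 10L))
  # the straddling block has 10 buildings, 3 in the zone
  bx <- c(seq(5, 25, length.out = 3), seq(35, 55, length.out = 7))
  buildings <- tibble::tibble(x = bx, y = 75, county_id = "C01")
  list(zone = zone, water = water, blocks = blocks, buildings = buildings)
}

test_that("block zone fractions match hand-computed areas and building counts", {
  s <- hand_scene()
  fr <- block_zone_fractions(s$blocks, s$zone, s$buildings, s$water)
  expect_equal(fr$fraction_area, c(1, 0, 0.5))  # 3 of 6 columns of "half"
  expect_equal(fr$n_buildings, c(0L, 0L, 10L))
  expect_equal(fr$buildings_in_zone, c(0L, 0L, 3L))
  expect_equal(fr$fraction_buildings, c(NA, NA, 0.3))
  expect_equal(fr$dry_area_m2, c(1000, 2500, 3000))
})

test_that("both density assumptions weight block populations by their fraction", {
  s <- hand_scene()
  eu <- estimate_zone_population(s$blocks, s$zone, s$buildings, "uniform",
                                 s$water)
  eb <- estimate_zone_population(s$blocks, s$zone, s$buildings, "building",
                                 s$water)
  expect_equal(eu$blocks$est_total, c(40, 0, 50))
  expect_equal(eb$blocks$est_total, c(40, 0, 30))   # 100 x 3/10 buildings
  expect_equal(eb$blocks$est_black, c(10, 0, 9))    # same fraction as total
  expect_equal(region_total(eu), 90)
  expect_equal(region_total(eb), 70)
  # fully-in and fully-out blocks carry no interpolation at all
  expect_equal(eu$blocks$fraction_used[1:2], eb$blocks$fraction_used[1:2])
})

test_that("a building-free straddling block falls back to its area fraction", {
  s <- hand_scene()
  bld <- s$buildings[s$buildings$x > 100, ]  # none left
  eb <- estimate_zone_population(s$blocks, s$zone, bld, "building", s$water)
  expect_true(eb$blocks$fallback_uniform[s$blocks$block_id == "half"])
  expect_equal(eb$blocks$est_total[3], 50)
  expect_false(any(eb$blocks$fallback_uniform[1:2]))
})

test_that("blocks with no dry land are flagged and contribute nothing", {
  s <- hand_scene()
  water <- s$water
  water[, 1:5] <- TRUE  # drown the southern half: block "in" is all water
  zone <- delineate_low_land(
    cp_grid(matrix(ifelse(row(matrix(0, 10, 10)) <= 3, 0, 5), 10, 10),
            cellsize = 10), 1, water)
  expect_warning(fr <- block_zone_fractions(s$blocks, zone, s$buildings,
                                            water),
                 "no dry land")
  expect_true(fr$zero_dry[fr$block_id == "in"])
  expect_equal(fr$fraction_area[fr$block_id == "in"], 0)
})

test_that("zone estimates add up across blocks, counties, and the region", {
  b <- medium_bundle()
  z <- zone_at(b, 1, 2020)
  blk <- blocks_of_year(b, 2020)
  est <- suppressWarnings(
    estimate_zone_population(blk, z, b$buildings, "building", b$water))
  cty <- est$totals[est$totals$scope == "county", ]
  expect_equal(sum(cty$est_total), region_total(est))
  expect_equal(region_total(est), sum(est$blocks$est_total))
  by_blk <- tapply(est$blocks$est_total, est$blocks$county_id, sum)
  expect_equal(as.vector(by_blk[cty$county_id]), cty$est_total)
  # subgroup estimates use the block's shared fraction
  expect_equal(est$blocks$est_black,
               est$blocks$pop_black * est$blocks$fraction_used)
})

test_that("in the census limit the interpolation is exact", {
  b <- small_bundle()
  whole <- coastpop:::new_hazard_zone(matrix(TRUE, b$elev$nx, b$elev$ny),
                                      b$elev, zone_type = "elevation",
                                      threshold_z_m = 99)
  blk <- blocks_of_year(b, 1990)
  for (m in c("uniform", "building")) {
    est <- suppressWarnings(
      estimate_zone_population(blk, whole, b$buildings, m, b$water))
    expect_equal(region_total(est), sum(blk$pop_total))
  }
})

test_that("census remapping leaves building-based totals exactly unchanged", {
  b <- medium_bundle()
  z <- zone_at(b, 1, 2020)
  blk <- blocks_of_year(b, 1990)
  rects <- blk[c("block_id", "county_id", "xmin", "xmax", "ymin", "ymax")]
  set.seed(31)
  split <- split_blocks(rects, b$buildings, prob = 0.3)
  expect_gt(nrow(split), nrow(rects))
  # retally the same persons on the new block geometry
  blk2 <- coastpop:::make_block_table(split, b$persons, b$buildings, 1990)
  tot <- function(blocks, method) {
    region_total(suppressWarnings(
      estimate_zone_population(blocks, z, b$buildings, method, b$water)))
  }
  expect_identical(tot(blk2, "building") - tot(blk, "building"), 0)
  expect_false(tot(blk2, "uniform") == tot(blk, "uniform"))
})

test_that("dasymetric refinement tightens the bracketing bounds", {
  b <- medium_bundle()
  z <- zone_at(b, 1, 2020)
  blk <- blocks_of_year(b, 2020)
  fr <- suppressWarnings(block_zone_fractions(blk, z, b$buildings, b$water))
  pvc <- suppressWarnings(
    partially_vulnerable_census(blk, z, b$buildings, b$water))
  lower <- pvc$pop_total[pvc$class == "entirely_in_zone"]
  upper <- sum(blk$pop_total[fr$fraction_area > 0])
  for (m in c("uniform", "building")) {
    est <- region_total(suppressWarnings(
      estimate_zone_population(blk, z, b$buildings, m, b$water)))
    expect_gte(est, lower)
    expect_lte(est, upper)
  }
  expect_gte(pvc$pop_total[pvc$class == "all_or_part_in_zone"], lower)
})

test_that("blocks lying off the grid raise a coordinate-mismatch error", {
  s <- hand_scene()
  bad <- s$blocks
  bad$xmin[1] <- 500; bad$xmax[1] <- 600
  expect_error(block_zone_fractions(bad, s$zone, s$buildings, s$water),
               "coordinate mismatch")
  expect_error(
    estimate_zone_population(dplyr::mutate(s$blocks,
                                           census_year = c(2010L, 2020L,
                                                           2020L)),
                             s$zone, s$buildings, "uniform", s$water),
    "single census year")
})
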