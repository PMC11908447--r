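test_that("block rectangles tile each county exactly", {
  b <- small_bundle()
  blk <- blocks_of_year(b, 1990)
  cty <- b$counties
  expect_equal(sum(blk$area_m2),
               sum((cty$xmax - cty$xmin) * (cty$ymax - cty$ymin)))
  # every grid cell belongs to exactly one block (raster has no gaps)
  braster <- coastpop:::block_cell_raster(b$elev, blk)
  expect_true(all(braster >= 1L))
})

test_that("block population counts are exact tallies of the ground-truth persons", {
  b <- small_bundle()
  for (yy in b$config$census_years) {
    blk <- blocks_of_year(b, yy)
    p <- b$persons[b$persons$census_year == yy, ]
    expect_equal(sum(blk$pop_total), nrow(p))
    expect_equal(sum(blk$pop_black), sum(p$subgroup == "black"))
    expect_equal(sum(blk$pop_hispanic), sum(p$subgroup == "hispanic"))
    # per-block recount through independent point-in-rectangle assignment
    pid <- assign_blocks(p$x, p$y, blk)
    recount <- as.integer(table(factor(pid, levels = blk$block_id)))
    expect_equal(blk$pop_total, recount)
  }
  expect_true(all(b$blocks$pop_black + b$blocks$pop_hispanic <=
                    b$blocks$pop_total))
})

test_that("the generator is a pure function of its configuration", {
  cfg <- small_config(seed = 99L)
  b1 <- generate_region(cfg)
  b2 <- generate_region(cfg)
  expect_identical(b1$blocks, b2$blocks)
  expect_identical(b1$persons, b2$persons)
  expect_identical(b1$buildings, b2$buildings)
  expect_identical(b1$elev$values, b2$elev$values)
  b3 <- generate_region(small_config(seed = 100L))
  expect_false(identical(b1$persons, b3$persons))
})

test_that("full placement bias keeps every building at or above its block's median dry elevation", {
  b <- generate_region(small_config(seed = 5L, placement_bias = 1),
                       all_years = FALSE)
  blk <- blocks_of_year(b, 1990)
  braster <- coastpop:::block_cell_raster(b$elev, blk)
  dry <- !b$water
  bid <- match(assign_blocks(b$buildings$x, b$buildings$y, blk), blk$block_id)
  low <- vapply(seq_len(nrow(b$buildings)), function(k) {
    med <- median(b$elev$values[braster == bid[k] & dry])
    b$buildings$elev[k] < med
  }, TRUE)
  expect_equal(sum(low), 0L)
})

test_that("zero placement bias gives elevation-uniform building placement over dry land", {
  # Under bias 0, the buildings of a block are a uniform draw from its dry
  # cells; a KS test against resampled dry-cell elevations should fail to
  # reject across seeds.
  rejections <- 0L
  for (s in 1:10) {
    b <- generate_region(small_config(seed = 300L + s, placement_bias = 0),
                         all_years = FALSE)
    blk <- blocks_of_year(b, 1990)
    braster <- coastpop:::block_cell_raster(b$elev, blk)
    dry <- !b$water
    bid <- match(assign_blocks(b$buildings$x, b$buildings$y, blk),
                 blk$block_id)
    set.seed(1000L + s)
    ref <- unlist(lapply(seq_len(nrow(blk)), function(j) {
      nb <- sum(bid == j)
      if (nb == 0L) return(numeric())
      cells <- which(braster == j & dry)
      b$elev$values[cells[sample.int(length(cells), nb, replace = TRUE)]]
    }))
    p <- suppressWarnings(stats::ks.test(b$buildings$elev, ref)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("a region with frozen dynamics repeats its census unchanged", {
  cfg <- small_config(seed = 11L, split_prob = 0,
                      migration = list(rate = 0, elev_threshold_m = 1,
                                       growth_rate = 0))
  b <- generate_region(cfg)
  y1 <- blocks_of_year(b, 1990)
  y2 <- blocks_of_year(b, 2000)
  expect_equal(y1$pop_total, y2$pop_total)
  expect_equal(y1$block_id, y2$block_id)
  expect_equal(y1[c("xmin", "xmax", "ymin", "ymax")],
               y2[c("xmin", "xmax", "ymin", "ymax")])
})

test_that("decadal emigration removes only low-lying persons and is logged exactly", {
  cfg <- small_config(seed = 13L, split_prob = 0,
                      migration = list(rate = 0.15, elev_threshold_m = 1,
                                       growth_rate = 0))
  b <- generate_region(cfg)
  p1 <- b$persons[b$persons$census_year == 1990, ]
  p2 <- b$persons[b$persons$census_year == 2000, ]
  log <- b$migration_log[b$migration_log$subgroup == "total", ]
  expect_equal(nrow(p1) - nrow(p2), sum(log$removed))
  expect_gt(sum(log$removed), 0)
  expect_equal(sum(log$added), 0)
  # persons at or above the threshold are untouched
  rel1 <- b$elev$values[p1$cell] - b$tidal$values[p1$cell]
  rel2 <- b$elev$values[p2$cell] - b$tidal$values[p2$cell]
  expect_equal(sum(rel2 >= 1), sum(rel1 >= 1))
})

test_that("census remapping carves an undeveloped part off each split block", {
  b <- small_bundle()
  blk <- blocks_of_year(b, 1990)
  rects <- blk[c("block_id", "county_id", "xmin", "xmax", "ymin", "ymax")]
  set.seed(21)
  split <- split_blocks(rects, b$buildings, prob = 1)
  expect_gt(nrow(split), nrow(rects))
  # total area is preserved
  area <- function(r) sum((r$xmax - r$xmin) * (r$ymax - r$ymin))
  expect_equal(area(split), area(rects))
  # for each parent with buildings, one child holds them all
  bid_new <- assign_blocks(b$buildings$x, b$buildings$y, split)
  parent <- sub("[ab]$", "", bid_new)
  bid_old <- assign_blocks(b$buildings$x, b$buildings$y, rects)
  expect_equal(parent, bid_old)
  per_child <- table(bid_new)
  for (pb in unique(bid_old[!is.na(bid_old)])) {
    kids <- per_child[c(paste0(pb, "a"), paste0(pb, "b"))]
    kids[is.na(kids)] <- 0
    expect_equal(as.integer(min(kids)), 0L)
  }
})

test_that("degenerate configurations are rejected with clear errors", {
  expect_error(region_config(county_size_km = c(0, 5)), "degenerate")
  expect_error(region_config(census_years = 2020L), "at least two")
  expect_error(region_config(census_years = c(2000L, 1990L)), "increasing")
  expect_error(region_config(subgroup_mix = list(p_black = 0.8,
                                                 p_hispanic = 0.4,
                                                 elev_gradient = 0)),
               "proportions")
  expect_error(region_config(placement_bias = 1.2), "placement_bias")
})

test_that("the adversarial uniform person mode scatters persons over dry land", {
  b <- generate_region(small_config(seed = 17L, person_mode = "uniform"),
                       all_years = FALSE)
  p <- b$persons[b$persons$census_year == 1990, ]
  expect_equal(nrow(p), 600L)
  expect_true(all(is.na(p$building_id)))
  expect_true(all(!b$water[p$cell]))
})
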