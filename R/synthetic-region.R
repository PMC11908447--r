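#' Generate a synthetic coastal region with person-level ground truth
#'
#' Builds a self-consistent region bundle: county and block polygons
#' (axis-aligned rectangles in a projected, meter-based plane), a ground
#' elevation grid, tidal-offset and rise-rate surfaces, a water mask over the
#' low coastal fringe, synthetic mapped floodplain polygons, building
#' locations biased away from low ground, and individual persons with
#' subgroup labels placed at building centroids (or uniformly over dry land
#' in the adversarial mode). Block population counts are exact tallies of the
#' contained persons, so every downstream estimate can be compared with the
#' true point-in-zone count.
#'
#' @param config a [region_config()].
#' @param all_years if `TRUE` (default) the remaining census years are
#'   generated immediately by repeated [advance_census()]; if `FALSE` only
#'   the first census year is present.
#' @return an object of class `region_bundle`: a list with elements
#'   `config`, `counties`, `blocks` (one row per block per census year),
#'   `buildings`, `persons` (one row per person per census year), grids
#'   `elev`, `tidal`, `rate`, the logical `water` mask, `floodplains`, and
#'   `migration_log`.
#' @export
generate_region <- function(config, all_years = TRUE) {
  validate_region_config(config)
  cs <- config$cellsize_m
  w_m <- config$county_size_km[1] * 1000
  h_m <- config$county_size_km[2] * 1000

  counties <- tibble(
    county_id = sprintf("C%02d", seq_len(config$n_counties)),
    xmin = (seq_len(config$n_counties) - 1) * w_m, xmax = seq_len(config$n_counties) * w_m,
    ymin = 0, ymax = h_m)

  nx <- as.integer(round(config$n_counties * w_m / cs))
  ny <- as.integer(round(h_m / cs))
  elev <- with_subseed(config$seed, "terrain", {
    cc_x <- (seq_len(nx) - 0.5) * cs
    cc_y <- (seq_len(ny) - 0.5) * cs
    base <- config$terrain$base_offset_m +
      config$terrain$slope_m_per_km * outer(rep(1, nx), cc_y) / 1000
    noise <- matrix(0, nx, ny)
    if (config$terrain$noise_amp_m > 0) {
      for (k in 1:4) {
        lambda <- runif(1, 500, 2500)
        theta <- runif(1, 0, pi)
        phi <- runif(1, 0, 2 * pi)
        noise <- noise + sin(2 * pi * (outer(cc_x * cos(theta), rep(1, ny)) +
                                         outer(rep(1, nx), cc_y * sin(theta))) /
                               lambda + phi)
      }
      noise <- noise * config$terrain$noise_amp_m / 2
    }
    cp_grid(base + noise, origin = c(0, 0), cellsize = cs)
  })

  tidal <- grid_like(elev, matrix(config$tidal_offset_m, nx, ny))
  rate <- if (is.data.frame(config$rise_rate_mm_per_yr)) {
    interpolate_rise_rates(config$rise_rate_mm_per_yr, elev)
  } else {
    grid_like(elev, matrix(config$rise_rate_mm_per_yr, nx, ny))
  }
  # Open water / wetland: ground at or below the tidal datum of the epoch
  # midpoint. With modest relief this is a contiguous fringe along y = 0.
  water <- (elev$values - tidal$values) <= 0

  block_rects <- dplyr::bind_rows(lapply(seq_len(nrow(counties)), function(i) {
    with_subseed(config$seed, "blocks", extra = i, {
      r <- guillotine_rects(counties$xmin[i], counties$xmax[i],
                            counties$ymin[i], counties$ymax[i],
                            config$blocks_per_county, cs)
      r$block_id <- sprintf("%s-B%03d", counties$county_id[i], seq_len(nrow(r)))
      r$county_id <- counties$county_id[i]
      r
    })
  }))

  blk_raster <- block_cell_raster(elev, block_rects)
  dry <- !water

  buildings <- dplyr::bind_rows(lapply(seq_len(nrow(counties)), function(i) {
    with_subseed(config$seed, "buildings", extra = i, {
      place_buildings(config, counties$county_id[i], block_rects, blk_raster,
                      elev, dry, cs)
    })
  }))
  buildings$building_id <- seq_len(nrow(buildings))

  year1 <- config$census_years[1]
  persons <- dplyr::bind_rows(lapply(seq_len(nrow(counties)), function(i) {
    with_subseed(config$seed, "persons", extra = i, {
      place_persons(config, counties$county_id[i], block_rects, blk_raster,
                    buildings, elev, dry, cs, year1)
    })
  }))
  persons$person_id <- seq_len(nrow(persons))

  floodplains <- with_subseed(config$seed, "floodplains", {
    synth_floodplains(counties)
  })

  blocks <- make_block_table(block_rects, persons, buildings, year1)

  bundle <- structure(list(
    config = config, counties = counties, blocks = blocks,
    buildings = buildings, persons = persons,
    elev = elev, tidal = tidal, rate = rate, water = water,
    floodplains = floodplains,
    migration_log = tibble(census_year = integer(), county_id = character(),
                           subgroup = character(), removed = integer(),
                           added = integer()),
    next_person_id = nrow(persons) + 1L
  ), class = "region_bundle")

  if (all_years) {
    while (max(bundle$persons$census_year) < max(config$census_years)) {
      bundle <- advance_census(bundle)
    }
  }
  bundle
}

#' @export
print.region_bundle <- function(x, ...) {
  yrs <- sort(unique(x$blocks$census_year))
  cat(sprintf("<region_bundle: %d counties, %d blocks, %d buildings, censuses %s>\n",
              nrow(x$counties), length(unique(x$blocks$block_id)),
              nrow(x$buildings), paste(yrs, collapse = ", ")))
  invisible(x)
}

# Recursive guillotine subdivision of a rectangle into n rectangles.
# Area-weighted choice of the rectangle to split gives an uneven, census-like
# size mix while guaranteeing an exact tiling.
# Cuts are snapped to the raster lattice so that no cell straddles a block
# boundary: cell-center membership and exact point-in-rectangle membership
# then agree for everything generated inside a cell.
guillotine_rects <- function(xmin, xmax, ymin, ymax, n, cellsize) {
  snap <- function(v) round(v / cellsize) * cellsize
  m <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("xmin", "xmax", "ymin", "ymax")))
  m[1, ] <- c(xmin, xmax, ymin, ymax)
  k <- 1L
  tries <- 0L
  while (k < n && tries < 50L * n) {
    tries <- tries + 1L
    area <- (m[1:k, 2] - m[1:k, 1]) * (m[1:k, 4] - m[1:k, 3])
    i <- sample.int(k, 1L, prob = area)
    r <- m[i, ]
    f <- runif(1, 0.3, 0.7)
    horiz <- (r[2] - r[1]) >= (r[4] - r[3])
    lo <- if (horiz) r[1] else r[3]
    hi <- if (horiz) r[2] else r[4]
    cut <- snap(lo + f * (hi - lo))
    cut <- min(max(cut, lo + cellsize), hi - cellsize)
    if (cut <= lo || cut >= hi) next  # too thin to split along this axis
    k <- k + 1L
    if (horiz) {
      m[i, ] <- c(r[1], cut, r[3], r[4])
      m[k, ] <- c(cut, r[2], r[3], r[4])
    } else {
      m[i, ] <- c(r[1], r[2], r[3], cut)
      m[k, ] <- c(r[1], r[2], cut, r[4])
    }
  }
  as_tibble(as.data.frame(m[seq_len(k), , drop = FALSE]))
}

# Integer raster assigning each cell (by its center) to a block row index.
block_cell_raster <- function(g, block_rects) {
  out <- matrix(0L, g$nx, g$ny)
  cc <- cell_centers(g)
  for (b in seq_len(nrow(block_rects))) {
    ix <- which(cc$x >= block_rects$xmin[b] & cc$x < block_rects$xmax[b])
    iy <- which(cc$y >= block_rects$ymin[b] & cc$y < block_rects$ymax[b])
    if (length(ix) && length(iy)) out[ix, iy] <- b
  }
  out
}

place_buildings <- function(config, county, block_rects, blk_raster,
                            elev, dry, cs) {
  in_cty <- which(block_rects$county_id == county)
  # development intensity varies across blocks (lognormal), so housing-unit
  # densities span the strata used in sample validation
  dry_cells <- lapply(in_cty, function(b) which(blk_raster == b & dry))
  w <- vapply(dry_cells, length, 0L) * stats::rlnorm(length(in_cty), 0, 1.2)
  if (all(w == 0)) abort("county has no dry land to develop")
  n_b <- as.vector(stats::rmultinom(1, config$buildings_per_county, w))
  res <- vector("list", length(in_cty))
  for (j in seq_along(in_cty)) {
    if (n_b[j] == 0L) next
    cells <- dry_cells[[j]]
    ev <- elev$values[cells]
    high <- cells[ev >= median(ev)]
    pick_high <- runif(n_b[j]) < config$placement_bias
    chosen <- integer(n_b[j])
    if (any(pick_high)) chosen[pick_high] <- high[sample.int(length(high), sum(pick_high), replace = TRUE)]
    if (any(!pick_high)) chosen[!pick_high] <- cells[sample.int(length(cells), sum(!pick_high), replace = TRUE)]
    ix <- (chosen - 1L) %% elev$nx + 1L
    iy <- (chosen - 1L) %/% elev$nx + 1L
    res[[j]] <- tibble(
      county_id = county,
      x = elev$origin[1] + (ix - 0.5 + runif(n_b[j], -0.45, 0.45)) * cs,
      y = elev$origin[2] + (iy - 0.5 + runif(n_b[j], -0.45, 0.45)) * cs,
      cell = chosen, elev = elev$values[chosen])
  }
  dplyr::bind_rows(res)
}

place_persons <- function(config, county, block_rects, blk_raster, buildings,
                          elev, dry, cs, year) {
  n <- config$persons_per_county
  if (config$person_mode == "buildings") {
    bl <- buildings[buildings$county_id == county, ]
    idx <- sample.int(nrow(bl), n, replace = TRUE)
    p <- tibble(census_year = year, county_id = county,
                x = bl$x[idx], y = bl$y[idx], cell = bl$cell[idx],
                building_id = bl$building_id[idx])
  } else {
    in_cty <- which(block_rects$county_id == county)
    cells <- which(matrix(blk_raster %in% in_cty, elev$nx, elev$ny) & dry)
    chosen <- cells[sample.int(length(cells), n, replace = TRUE)]
    ix <- (chosen - 1L) %% elev$nx + 1L
    iy <- (chosen - 1L) %/% elev$nx + 1L
    p <- tibble(census_year = year, county_id = county,
                x = elev$origin[1] + (ix - 0.5 + runif(n, -0.45, 0.45)) * cs,
                y = elev$origin[2] + (iy - 0.5 + runif(n, -0.45, 0.45)) * cs,
                cell = chosen, building_id = NA_integer_)
  }
  p$subgroup <- draw_subgroups(config, county, elev$values[p$cell],
                               buildings, elev)
  p
}

# Subgroup labels are mutually exclusive classes: non-Hispanic Black,
# Hispanic (any race), other. The Black share rises on low ground when
# elev_gradient > 0 (per-meter log scale around the county building mean).
draw_subgroups <- function(config, county, person_elev, buildings, elev) {
  i <- match(county, sprintf("C%02d", seq_len(config$n_counties)))
  pb <- rep_len(config$subgroup_mix$p_black, config$n_counties)[i]
  ph <- rep_len(config$subgroup_mix$p_hispanic, config$n_counties)[i]
  g <- config$subgroup_mix$elev_gradient %||% 0
  ebar <- mean(buildings$elev[buildings$county_id == county])
  if (!is.finite(ebar)) ebar <- mean(elev$values, na.rm = TRUE)
  wb <- pb * exp(g * (ebar - person_elev))
  wh <- rep(ph, length(person_elev))
  wo <- rep(max(1 - pb - ph, 1e-6), length(person_elev))
  tot <- wb + wh + wo
  u <- runif(length(person_elev)) * tot
  ifelse(u < wb, "black", ifelse(u < wb + wh, "hispanic", "other"))
}

# Seeded synthetic "mapped floodplain" polygons: an A (100-year) band along
# the shore and an X500 (500-year) band just inland of it, per county. The
# mapped product is deliberately imperfect relative to terrain, as real
# floodplain layers are.
synth_floodplains <- function(counties) {
  res <- vector("list", nrow(counties))
  for (i in seq_len(nrow(counties))) {
    wx <- counties$xmax[i] - counties$xmin[i]
    x0 <- counties$xmin[i] + runif(1, 0.05, 0.2) * wx
    x1 <- counties$xmax[i] - runif(1, 0.05, 0.2) * wx
    y_lo <- runif(1, 100, 300)
    y_mid <- y_lo + runif(1, 400, 900)
    y_hi <- y_mid + runif(1, 300, 600)
    res[[i]] <- tibble(
      county_id = counties$county_id[i],
      category = c("A", "X500"),
      xmin = x0, xmax = x1,
      ymin = c(y_lo, y_mid), ymax = c(y_mid, y_hi))
  }
  out <- dplyr::bind_rows(res)
  out$poly_id <- sprintf("FP%02d", seq_len(nrow(out)))
  out
}

#' Assign points to blocks by rectangle membership
#'
#' Half-open convention: a point belongs to the block with
#' `xmin <= x < xmax` and `ymin <= y < ymax`, so a tiling of rectangles
#' assigns every interior point to exactly one block.
#'
#' @param x,y point coordinates (m).
#' @param block_rects tibble with `block_id`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @return character vector of block ids (`NA` outside all blocks).
#' @export
assign_blocks <- function(x, y, block_rects) {
  out <- rep(NA_character_, length(x))
  for (b in seq_len(nrow(block_rects))) {
    hit <- is.na(out) & x >= block_rects$xmin[b] & x < block_rects$xmax[b] &
      y >= block_rects$ymin[b] & y < block_rects$ymax[b]
    out[hit] <- block_rects$block_id[b]
  }
  out
}

# Tally a census-year block table from ground truth.
make_block_table <- function(block_rects, persons, buildings, year) {
  p <- persons[persons$census_year == year, ]
  pid <- assign_blocks(p$x, p$y, block_rects)
  bid <- assign_blocks(buildings$x, buildings$y, block_rects)
  tab <- block_rects
  tab$census_year <- year
  tab$area_m2 <- (tab$xmax - tab$xmin) * (tab$ymax - tab$ymin)
  tab$pop_total <- as.integer(table(factor(pid, levels = tab$block_id)))
  tab$pop_black <- as.integer(table(factor(pid[p$subgroup == "black"],
                                           levels = tab$block_id)))
  tab$pop_hispanic <- as.integer(table(factor(pid[p$subgroup == "hispanic"],
                                              levels = tab$block_id)))
  tab$housing_units <- as.integer(table(factor(bid, levels = tab$block_id)))
  tab[, c("block_id", "county_id", "census_year", "xmin", "xmax", "ymin",
          "ymax", "area_m2", "pop_total", "pop_black", "pop_hispanic",
          "housing_units")]
}

#' Advance a region bundle to the next census year
#'
#' Applies one decade of dynamics: elevation- and county-conditional
#' emigration (persons below the configured sea-level-relative threshold are
#' removed with the configured probability, optionally amplified per
#' subgroup), proportional in-migration at random buildings, and census
#' remapping in which a fraction of blocks is subdivided by carving off an
#' undeveloped part (all buildings and persons stay in the developed part,
#' the typical real-world remapping). The new census year's block table is
#' tallied from the surviving ground-truth persons.
#'
#' @param region a `region_bundle`.
#' @param decade_rules optional override of `config$migration` for this
#'   decade (same structure).
#' @return the bundle with the next configured census year appended.
#' @export
advance_census <- function(region, decade_rules = NULL) {
  cfg <- region$config
  years <- cfg$census_years
  cur <- max(region$persons$census_year)
  pos <- match(cur, years)
  if (is.na(pos) || pos == length(years)) {
    abort("no next census year configured after the current one")
  }
  nxt <- years[pos + 1L]
  mig <- decade_rules %||% cfg$migration

  p <- region$persons[region$persons$census_year == cur, ]
  rel <- region$elev$values[p$cell] - region$tidal$values[p$cell]
  cmult <- rep_len(mig$county_multiplier %||% 1, cfg$n_counties)
  names(cmult) <- region$counties$county_id
  smult <- c(black = 1, hispanic = 1, other = 1)
  sm <- mig$subgroup_multiplier %||% numeric()
  smult[names(sm)] <- sm
  p_rem <- ifelse(rel < (mig$elev_threshold_m %||% 1),
                  pmin((mig$rate %||% 0) * cmult[p$county_id] *
                         smult[p$subgroup], 1), 0)

  new_persons <- with_subseed(cfg$seed, "advance", extra = nxt, {
    gone <- runif(nrow(p)) < p_rem
    removed <- p[gone, ]
    stay <- p[!gone, ]
    added <- NULL
    gr <- mig$growth_rate %||% 0
    if (gr > 0) {
      added <- dplyr::bind_rows(lapply(region$counties$county_id, function(cty) {
        n_cty <- sum(stay$county_id == cty)
        n_new <- rbinom(1, n_cty, gr)
        if (n_new == 0L) return(NULL)
        bl <- region$buildings[region$buildings$county_id == cty, ]
        idx <- sample.int(nrow(bl), n_new, replace = TRUE)
        tibble(census_year = nxt, county_id = cty,
               x = bl$x[idx], y = bl$y[idx], cell = bl$cell[idx],
               building_id = bl$building_id[idx],
               subgroup = draw_subgroups(cfg, cty, region$elev$values[bl$cell[idx]],
                                         region$buildings, region$elev),
               person_id = NA_integer_)
      }))
    }
    list(removed = removed, stay = stay, added = added)
  })

  stay <- new_persons$stay
  stay$census_year <- nxt
  added <- new_persons$added
  if (!is.null(added) && nrow(added) > 0) {
    added$person_id <- seq(region$next_person_id, length.out = nrow(added))
    region$next_person_id <- region$next_person_id + nrow(added)
  }
  next_p <- dplyr::bind_rows(stay, added)

  # census remapping: carve undeveloped parts off a fraction of blocks
  cur_rects <- region$blocks[region$blocks$census_year == cur,
                             c("block_id", "county_id", "xmin", "xmax",
                               "ymin", "ymax")]
  new_rects <- with_subseed(cfg$seed, "split", extra = nxt, {
    split_blocks(cur_rects, region$buildings, cfg$split_prob)
  })

  log_rows <- dplyr::bind_rows(lapply(region$counties$county_id, function(cty) {
    rem <- new_persons$removed
    add <- added %||% tibble(county_id = character(), subgroup = character())
    tibble(census_year = nxt, county_id = cty,
           subgroup = c("total", "black", "hispanic"),
           removed = c(sum(rem$county_id == cty),
                       sum(rem$county_id == cty & rem$subgroup == "black"),
                       sum(rem$county_id == cty & rem$subgroup == "hispanic")),
           added = c(sum(add$county_id == cty),
                     sum(add$county_id == cty & add$subgroup == "black"),
                     sum(add$county_id == cty & add$subgroup == "hispanic")))
  }))

  region$persons <- dplyr::bind_rows(region$persons, next_p)
  region$blocks <- dplyr::bind_rows(
    region$blocks, make_block_table(new_rects, region$persons,
                                    region$buildings, nxt))
  region$migration_log <- dplyr::bind_rows(region$migration_log, log_rows)
  region
}

#' Subdivide blocks the way census remapping does
#'
#' Each block is selected with probability `prob`; a selected block is cut
#' into a developed part containing all of its buildings and an undeveloped
#' part containing none (the cut falls in the empty margin between the
#' building bounding box and the block edge). Buildings and persons are
#' never moved, so a building-density interpolation of any fixed zone is
#' unaffected by the remapping while an area-based one generally is not.
#' Blocks with no buildings are cut at a uniform position.
#'
#' @param block_rects tibble with `block_id`, `county_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax`.
#' @param buildings building table with `x`, `y`.
#' @param prob per-block subdivision probability.
#' @return a tibble of rectangles in the same format; split blocks appear as
#'   two rows with suffixed ids.
#' @export
split_blocks <- function(block_rects, buildings, prob) {
  out <- vector("list", nrow(block_rects))
  pick <- runif(nrow(block_rects)) < prob
  for (b in seq_len(nrow(block_rects))) {
    r <- block_rects[b, ]
    if (!pick[b]) { out[[b]] <- r; next }
    inb <- buildings$x >= r$xmin & buildings$x < r$xmax &
      buildings$y >= r$ymin & buildings$y < r$ymax
    cut <- NULL
    if (any(inb)) {
      margins <- c(w = unname(min(buildings$x[inb]) - r$xmin),
                   e = unname(r$xmax - max(buildings$x[inb])),
                   s = unname(min(buildings$y[inb]) - r$ymin),
                   n = unname(r$ymax - max(buildings$y[inb])))
      side <- names(which.max(margins))
      f <- runif(1, 0.2, 0.8)
      cut <- switch(side,
        w = list(axis = "x", at = unname(r$xmin + f * margins[["w"]])),
        e = list(axis = "x", at = unname(r$xmax - f * margins[["e"]])),
        s = list(axis = "y", at = unname(r$ymin + f * margins[["s"]])),
        n = list(axis = "y", at = unname(r$ymax - f * margins[["n"]])))
    } else {
      cut <- list(axis = if (runif(1) < 0.5) "x" else "y", at = NA)
      cut$at <- unname(if (cut$axis == "x") (r$xmin + r$xmax) / 2
                       else (r$ymin + r$ymax) / 2)
    }
    if (cut$axis == "x") {
      a <- r; a$xmax <- cut$at; bpart <- r; bpart$xmin <- cut$at
    } else {
      a <- r; a$ymax <- cut$at; bpart <- r; bpart$ymin <- cut$at
    }
    a$block_id <- paste0(r$block_id, "a")
    bpart$block_id <- paste0(r$block_id, "b")
    out[[b]] <- dplyr::bind_rows(a, bpart)
  }
  dplyr::bind_rows(out)
}
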