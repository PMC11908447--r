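# Shared synthetic fixtures. Bundles are deterministic functions of their
# configuration, so they are generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, fast region: one county, two censuses.
small_config <- function(seed = 42L, ...) {
  region_config(seed = seed, n_counties = 1L, blocks_per_county = 30L,
                persons_per_county = 600L, buildings_per_county = 300L,
                county_size_km = c(2, 3), census_years = c(1990L, 2000L),
                ...)
}

small_bundle <- function() cached("small", generate_region(small_config()))

# A mid-sized region at the generator defaults (2 counties x 100 blocks,
# 5000 persons, 4 censuses), used by the estimation and trend tests.
medium_bundle <- function() {
  cached("medium", generate_region(region_config(seed = 7L)))
}

# Hazard zone of a bundle for threshold z and sea-level year.
zone_at <- function(bundle, z, year) {
  rel <- relative_elevation_grid(bundle$elev, bundle$tidal, bundle$rate, year)
  delineate_low_land(rel, z, bundle$water)
}

region_total <- function(est) {
  est$totals$est_total[est$totals$scope == "region"]
}

blocks_of_year <- function(bundle, year) {
  bundle$blocks[bundle$blocks$census_year == year, ]
}
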