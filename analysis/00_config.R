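# Shared settings for the analysis scripts. Each numbered script is a thin
# driver over the coastpop package: it regenerates the (deterministic)
# synthetic region from this configuration, computes one stage, and writes
# its tables under results/. Run them in order from the repository root:
#
#   Rscript analysis/01_generate_region.R
#   Rscript analysis/02_hazard_zones.R
#   ...

suppressPackageStartupMessages({
  library(coastpop)
  library(dplyr)
})

ANALYSIS_SEED <- 20260101L
RESULTS_DIR <- "results"

analysis_config <- function() {
  region_config(
    seed = ANALYSIS_SEED,
    n_counties = 4L,
    blocks_per_county = 150L,
    persons_per_county = 4000L,
    buildings_per_county = 1600L,
    census_years = c(1990L, 2000L, 2010L, 2020L))
}

analysis_bundle <- function() generate_region(analysis_config())

zone_for <- function(bundle, z, year) {
  rel <- relative_elevation_grid(bundle$elev, bundle$tidal, bundle$rate, year)
  delineate_low_land(rel, z, bundle$water)
}

results_path <- function(...) {
  dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
  file.path(RESULTS_DIR, ...)
}

write_table <- function(x, name) {
  path <- results_path(name)
  utils::write.csv(x, path, row.names = FALSE)
  message("wrote ", path)
}
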