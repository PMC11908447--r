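#!/usr/bin/env Rscript
# Stage 1: generate the synthetic coastal region (with person-level ground
# truth) and export its layers in open formats.

source("analysis/00_config.R")

bundle <- analysis_bundle()
print(bundle)

write_region_bundle(bundle, results_path("region"))
message("wrote ", results_path("region"), "/ (GeoJSON + ASCII grids)")

# headline tallies per county and census year
county_year <- bundle$blocks |>
  group_by(county_id, census_year) |>
  summarise(n_blocks = dplyr::n(),
            pop_total = sum(pop_total),
            pop_black = sum(pop_black),
            pop_hispanic = sum(pop_hispanic),
            housing_units = sum(housing_units),
            .groups = "drop")
write_table(county_year, "county_census_totals.csv")
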