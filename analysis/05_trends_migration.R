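#!/usr/bin/env Rscript
# Stage 5: the census-year x sea-level-year population matrix, the
# demographic/sea-level decomposition of the 30-year change, and county
# apparent-migration accounting.

source("analysis/00_config.R")

bundle <- analysis_bundle()
cfg <- bundle$config
years <- cfg$census_years
zones <- lapply(years, function(yy) zone_for(bundle, 1, yy))
names(zones) <- years

series <- suppressWarnings(
  zone_population_series(bundle$blocks, zones, bundle$buildings,
                         bundle$water, method = "building"))
tab <- as.data.frame.table(series$values, responseName = "population")
names(tab)[1:3] <- c("census_year", "sea_level_year", "subgroup")
write_table(tab, "zone_population_series_z1.csv")

dec <- dplyr::bind_rows(lapply(c("total", "black", "hispanic"), function(sg) {
  d <- decompose_change(series, min(years), max(years), subgroup = sg)
  tibble::tibble(subgroup = sg, d_census = d$d_census,
                 d_sea_level = d$d_sea_level, actual = d$actual,
                 cross_term = d$cross_term)
}))
print(dec)
write_table(dec, "decomposition_z1.csv")

# county-level apparent migration against the fixed terminal-year zone
zone_term <- zones[[as.character(max(years))]]
cty_zone <- suppressWarnings(
  county_zone_populations(bundle$blocks, zone_term, bundle$buildings,
                          bundle$water, method = "building"))
cty_pop <- bundle$blocks |>
  group_by(county_id, census_year) |>
  summarise(pop_total = sum(pop_total), pop_black = sum(pop_black),
            pop_hispanic = sum(pop_hispanic), .groups = "drop")
emig <- county_apparent_migration(cty_zone, cty_pop)
print(emig)
write_table(emig$by_decade, "apparent_migration_by_decade.csv")
write_table(emig$by_county, "apparent_migration_by_county.csv")
write_table(tibble::tibble(subgroup = sub("^change_", "", names(emig$national)),
                           apparent_emigration = unname(emig$national)),
            "apparent_migration_national.csv")
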