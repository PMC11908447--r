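#!/usr/bin/env Rscript
# Stage 6: racial disparity of hazard-zone residence and of apparent
# emigration, synthetic region and published-table arithmetic side by side.

source("analysis/00_config.R")

bundle <- analysis_bundle()
cfg <- bundle$config
year <- max(cfg$census_years)
blk <- bundle$blocks[bundle$blocks$census_year == year, ]
zone <- zone_for(bundle, 1, year)

est <- suppressWarnings(
  estimate_zone_population(blk, zone, bundle$buildings, "building",
                           bundle$water))
cty <- est$totals[est$totals$scope == "county", ]
cpop <- bundle$blocks |>
  filter(census_year == year) |>
  group_by(county_id) |>
  summarise(pop_total = sum(pop_total), pop_black = sum(pop_black),
            pop_hispanic = sum(pop_hispanic), .groups = "drop")
m <- inner_join(cty, cpop, by = "county_id")

residence <- dplyr::bind_rows(lapply(c("black", "hispanic"), function(sg) {
  tibble::tibble(
    subgroup = sg,
    nationwide_ratio = nationwide_disproportionality(
      c(total = sum(m$est_total), x = sum(m[[paste0("est_", sg)]])),
      c(total = sum(cpop$pop_total), x = sum(cpop[[paste0("pop_", sg)]])),
      subgroup = "x"),
    county_weighted_ratio = county_weighted_disproportionality(
      tibble::tibble(zone_subgroup = m[[paste0("est_", sg)]],
                     zone_total = m$est_total,
                     county_subgroup = m[[paste0("pop_", sg)]],
                     county_total = m$pop_total)))
}))
print(residence)
write_table(residence, "residence_disparity_z1.csv")

# emigration disparity from the generator's migration log (ground truth)
log <- bundle$migration_log
emig <- log |>
  group_by(county_id, subgroup) |>
  summarise(removed = sum(removed), .groups = "drop") |>
  tidyr::pivot_wider(names_from = subgroup, values_from = removed)
base <- bundle$blocks |>
  filter(census_year == min(cfg$census_years)) |>
  group_by(county_id) |>
  summarise(pop_total = sum(pop_total), pop_black = sum(pop_black),
            .groups = "drop")
d <- emigration_disparity(
  tibble::tibble(county_id = emig$county_id, emig_total = emig$total,
                 emig_subgroup = emig$black),
  tibble::tibble(county_id = base$county_id, pop_total = base$pop_total,
                 pop_subgroup = base$pop_black))
print(d)
write_table(tibble::tibble(
  share_emigration = d$share_emigration,
  share_population = d$share_population,
  nationwide_ratio = d$nationwide_ratio,
  county_weighted_ratio = d$county_weighted_ratio),
  "emigration_disparity.csv")

# published-table arithmetic for comparison
hz <- read_reference_table("hazard_zone_emigration_totals.csv")
hz$black_share <- hz$emig_black_thousand / hz$emig_total_thousand
write_table(hz, "published_emigration_shares.csv")
shares <- read_reference_table("residence_shares_below1m.csv")
published_ratio <- nationwide_disproportionality(
  c(total = 1, black = shares$black_share_zone),
  c(total = 1, black = shares$black_share_national))
message(sprintf("published nationwide residence ratio below 1 m: %.3f",
                published_ratio))
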