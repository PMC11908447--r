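# Data dictionary

## Shipped reference tables (`extdata/`)

### county_decadal_change_below1m_2020sl.csv
Published per-county decadal changes in the population living on dry land
less than 1 m above the 2020 sea level (building-based density), for the 21
US counties where apparent emigration exceeded 1% of county population,
1990-2020.

- `county_id`, `state` — county name and state postal code.
- `change_1990s`, `change_2000s`, `change_2010s` — decadal change in zone
  population (persons; negative = apparent emigration).
- `printed_total` — the published 30-year total. For a few counties this
  differs by one person from the sum of the printed decadal entries
  (rounding in the source); accounting checks use the internally
  consistent rows.

### hazard_zone_emigration_totals.csv
Published national apparent-emigration totals by hazard zone, 1990-2020
(thousands of persons), for all races and for Black residents.

### residence_shares_below1m.csv
Published shares used in the nationwide residence-disproportionality
ratio: the Black share of the population below 1 m and of the national
population (2020).

## Pipeline output CSVs (per-block estimates and totals)

`run_pipeline()` writes, under the output directory:

- `series_z<z>_<method>.csv` — zone-population totals for every
  (census year, sea-level year, subgroup) cell:
  `census_year`, `sea_level_year`, `subgroup`, `population`.
- `emigration_z<z>_<method>.csv` — per county: `change_total`,
  `change_black`, `change_hispanic` (30-year change in zone population),
  base-year county populations `pop_total`, `pop_black`, `pop_hispanic`,
  percent changes `pct_total`, `pct_black`, `pct_hispanic`, and `flagged`
  (apparent emigration above the threshold percent of county population).
- `disparity_z<z>.csv` — per subgroup: `nationwide_ratio`,
  `county_weighted_ratio` at the terminal census.
- `validation_cv.csv` — ratio-estimator report per method: `R_hat`, `se`,
  `cv`, `excludes_one`.
- `summary.csv` — one row per (z, method): terminal-year estimates,
  decomposition components (`d_census`, `d_sea_level`, `actual`,
  `cross_term`), and the national apparent-emigration total.

Per-block estimate columns (in `zone_estimate$blocks`): `dry_area_m2`,
`area_in_zone_m2`, `n_buildings`, `buildings_in_zone`, `fraction_area`,
`fraction_buildings`, `fraction_used`, `fallback_uniform` (zero-building
partial block fell back to the area fraction), `est_total`, `est_black`,
`est_hispanic`. Estimates are reals; round only at report time.
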