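#!/usr/bin/env Rscript
# Stage 2: delineate hazard zones (land below 1 m and 3 m of each census
# year's sea level) and classify the mapped floodplains coastal vs inland.

source("analysis/00_config.R")

bundle <- analysis_bundle()
cfg <- bundle$config

areas <- dplyr::bind_rows(lapply(c(1, 3), function(z) {
  dplyr::bind_rows(lapply(cfg$census_years, function(yy) {
    zone <- zone_for(bundle, z, yy)
    tibble::tibble(threshold_m = z, sea_level_year = yy,
                   n_cells = sum(zone$mask),
                   area_km2 = zone_area(zone) / 1e6)
  }))
}))
write_table(areas, "zone_areas.csv")

# export the terminal-year 1 m zone as polygons
z1 <- zone_for(bundle, 1, max(cfg$census_years))
write_rects_geojson(zone_to_rects(z1), results_path("zone_below1m_2020.geojson"))
message("wrote ", results_path("zone_below1m_2020.geojson"))

# floodplain classification against the 1992-epoch relative elevation
rel92 <- relative_elevation_grid(bundle$elev, bundle$tidal, bundle$rate, 1992)
fz <- classify_floodplain(bundle$floodplains, rel92, bfe = 1.5)
fp <- dplyr::bind_rows(lapply(names(fz), function(nm) {
  tibble::tibble(zone = nm, n_cells = sum(fz[[nm]]$mask),
                 area_km2 = zone_area(fz[[nm]]) / 1e6)
}))
write_table(fp, "floodplain_classes.csv")
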