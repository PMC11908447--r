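#!/usr/bin/env Rscript
# Stage 4: validate both interpolation methods with a stratified block
# sample scored by the combined ratio estimator (observed / estimated).

source("analysis/00_config.R")

bundle <- analysis_bundle()
year <- min(bundle$config$census_years)
blk <- bundle$blocks[bundle$blocks$census_year == year, ]
zone <- zone_for(bundle, 1, year)
fr <- suppressWarnings(
  block_zone_fractions(blk, zone, bundle$buildings, bundle$water))
truth <- true_zone_counts(bundle, zone, year)

strata <- stratify_blocks(blk, fr,
                          strata_rules(density_breaks = c(0.15, 0.5, 1.5)))
N_h <- attr(strata, "sizes")
sizes <- setNames(pmin(N_h, pmax(2L, ceiling(0.5 * N_h))), names(N_h))
message(sprintf("sampling %d of %d candidate blocks across %d strata",
                sum(sizes), sum(N_h), length(N_h)))

ests <- lapply(c(uniform = "uniform", building = "building"), function(m) {
  e <- suppressWarnings(
    estimate_zone_population(blk, zone, bundle$buildings, m, bundle$water))
  s <- draw_sample(strata, sizes, seed = ANALYSIS_SEED + 1L)
  s$y <- truth$true_in_zone[match(s$block_id, truth$block_id)]
  s$x <- e$blocks$est_total[match(s$block_id, e$blocks$block_id)]
  frame_x <- sum(e$blocks$est_total[e$blocks$block_id %in% strata$block_id])
  suppressWarnings(
    combined_ratio_estimate(s, N_h = N_h[names(sizes)], x_total = frame_x))
})
report <- cv_report(ests)
print(report)
write_table(report, "validation_cv.csv")
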