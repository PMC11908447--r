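Package: coastpop
Title: Population Exposure to Sea-Level Rise and Flood Hazard Zones
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the population living in small geographic hazard
    zones (dry land below a threshold elevation relative to a given year's
    sea level, or mapped 100-/500-year floodplains) from census-block
    counts by dasymetric areal interpolation, comparing the uniform-density
    assumption with a building-based density assumption. Includes a
    synthetic-region generator with person-level ground truth for
    validating the estimators; stratified block sampling with combined
    ratio estimators (Cochran) and coefficients of variation; decomposition
    of zone-population change into sea-level and demographic components;
    county-level apparent-emigration accounting; and nationwide versus
    county-weighted disproportionality ratios for residence in, and
    emigration from, hazard zones.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
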