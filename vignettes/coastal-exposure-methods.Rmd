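---
title: "Estimating population exposure to sea-level rise: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population exposure to sea-level rise: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastpop)
library(dplyr)
```

## The estimation problem

How many people live on land that is, or will soon be, below a given height
above sea level? Population counts are published for census blocks, but a
hazard zone — dry land below 1 m of a given year's sea level, say, or a
mapped floodplain — cuts through blocks. Some assumption is needed to
apportion a partially overlapped block's population, and the choice
matters: people do not live uniformly over their block, and in coastal
terrain they systematically avoid the lowest ground.

`coastpop` implements and compares the two standard dasymetric
(ancillary-data-refined) interpolation rules:

* **Uniform density** — the in-zone share of a block's population equals
  the in-zone share of its *dry land* area (open water and wetland are
  excluded from the denominator).
* **Building-based density** — the in-zone share equals the in-zone share
  of the block's *buildings* (by centroid). A partially overlapped block
  with no mapped buildings falls back to its area fraction and is flagged.

Subgroup counts (non-Hispanic Black, Hispanic) are apportioned with the
same per-block fraction as the total: the block is the finest resolution
at which composition is known, and inventing a finer pattern would be
unsupported.

## Elevation relative to a year's sea level

Ground elevation grids are referenced to a fixed vertical datum. Sea level
is the local tidal datum — mean higher high water (MHHW) — which varies in
space, and it rises over time at a locally varying rate. A cell's
elevation relative to the sea level of year $y$ is

$$\mathrm{rel}(y) \;=\; E \;-\; T \;-\; r\,(y - 1992)/1000,$$

with $E$ the ground elevation (m), $T$ the MHHW offset above the datum
(m), and $r$ the rise rate (mm/yr). 1992 is the midpoint of the tidal
epoch to which $T$ refers, so at $y = 1992$ the offset alone applies.

A hazard zone at threshold $z$ is the set of cells with
$\mathrm{rel}(y) < z$ (strict: ties at exactly $z$ are excluded), that are
not open water or wetland, with membership decided by the cell-center
value. Mapped floodplain polygons (100-year "A" and 500-year "X500"
categories) are instead classified *coastal* or *inland* by whether the
area-majority of a polygon's cells sits at or below the base flood
elevation.

All geometry is planar and in meters. Because the package targets
environments without compiled spatial libraries, polygons are axis-aligned
rectangles and rasters are plain numeric matrices; layers are exchanged as
GeoJSON (with a note that coordinates are planar meters) and ESRI ASCII
grids — both plain text. This loses nothing for the method: zone
membership, guillotine block geometry, and point-in-rectangle assignment
are exactly the operations the estimators need, and every one of them has
an exact, testable implementation on this substrate.

## The synthetic region and its ground truth

Real elevation and census data cannot ship with a package, and more
importantly they carry no ground truth: nobody knows the true number of
people below 1 m. The generator therefore builds regions where the truth
is *constructed*: every person is a point with coordinates, and block
counts are exact tallies of those points. Any estimator can then be scored
against the exact point-in-zone count (`true_zone_counts()`).

```{r generator, eval = FALSE}
cfg <- region_config(seed = 1)
bundle <- generate_region(cfg)
```

Design of the generator, and why:

* **Terrain.** Counties are rectangles side by side along a shared
  shoreline at $y = 0$; elevation is a tilted plane (rising inland) plus
  smooth seeded sinusoidal relief. With the relief amplitude set to zero,
  the area below a contour has a closed form — used as an analytic oracle
  in the tests. The wet fringe (ground at or below MHHW) becomes the water
  mask.
* **Blocks.** Recursive guillotine splits of the county rectangle, with
  area-weighted selection of the rectangle to split, produce the uneven,
  census-like mix of block sizes that stratified validation needs. Cuts
  are snapped to the raster lattice so no cell straddles a block boundary
  — cell-center membership and exact point-in-rectangle membership then
  agree, which keeps the ground truth exactly reconcilable with the
  raster-based estimators.
* **Buildings.** Each block gets a lognormal development intensity (so
  unit densities span the sampling strata), and each building is placed,
  with probability `placement_bias`, only on dry cells at or above its
  block's median dry elevation. This is the central realism choice: people
  build on the high part of the land. At bias 0 placement is uniform over
  dry land (verified by a Kolmogorov–Smirnov check in the tests); at bias
  1 no building sits below its block's median (verified exactly).
* **Persons.** In the default mode persons live at building centroids —
  the generative model under which the building-based estimator is
  correctly specified. The adversarial `person_mode = "uniform"` scatters
  them over dry land instead, which is the world in which the uniform
  assumption would be right; comparing the two modes separates "the
  estimator is right" from "the generator favors it".
* **Subgroups.** Per-county Black and Hispanic proportions, with an
  optional elevation gradient that concentrates the Black share on low
  ground — emulating the settlement patterns that make exposure
  disparities possible in the first place.
* **Dynamics.** Between censuses, persons below an elevation threshold
  emigrate with a configurable probability (optionally amplified per
  county and per subgroup), growth adds persons at random buildings, and a
  fraction of blocks is *remapped*: an undeveloped margin is carved off,
  so all buildings and persons stay in the developed child. Every removal
  and addition is logged, so apparent-migration accounting can be checked
  against the generator's own books.

Known limits of the generator, accepted deliberately: rectangles cannot
represent convoluted shorelines or enclave blocks; buildings have no
footprint area (centroids only, which is also all the estimator uses);
tides and datum error are not simulated; and emigration is a simple
per-person Bernoulli process, not a behavioral model. None of these
affect what the synthetic region is for — scoring interpolation and
survey arithmetic against a known truth.

## Survey validation: the combined ratio estimator

Interpolated counts are model outputs; the validation design treats them
as the auxiliary variable $x$ and the true (ground-truth) count as $y$ on
a stratified simple random sample of *candidate* blocks — those partially
inside the zone, since fully-in and fully-out blocks carry no
interpolation error. Strata follow the classic design: a tiny-block
stratum below 0.25 ha, then housing-unit-density classes, with optional
special classes (e.g. protected/diked blocks) taking precedence.

The pooled estimate is the combined ratio estimator (Cochran's classical
survey-sampling treatment, §6.11–6.12):

$$\hat R_c = \frac{\sum_h N_h \bar y_h}{\sum_h N_h \bar x_h},
\qquad
V(\hat R_c) = \frac{1}{\hat X^2} \sum_h \frac{N_h^2 (1 - f_h)}{n_h}
  \left(s^2_{yh} + \hat R_c^2 s^2_{xh} - 2 \hat R_c s_{yxh}\right),$$

with finite-population corrections $1 - f_h$. The coefficient of
variation $\mathrm{se}(\hat R_c)/\hat R_c$ is read as a 66% confidence
range (±1 SE); a range excluding 1 means the method's predictions differ
detectably from the truth. Degenerate strata are handled loudly, not
silently: a stratum sampled with $n_h = 1$ contributes zero estimated
variance with a warning, and a stratum whose sampled $x$ are all zero
while $y$ is not is excluded with a warning.

The package's calibration test draws 500 independent stratified samples
from one synthetic region and checks that the ratio-adjusted total is
unbiased within Monte-Carlo error and that the nominal 66% intervals
cover the truth at close to — in practice slightly below — their nominal
rate, the familiar behavior of large-sample ratio variances at moderate
$n$ with skewed residuals.

## Trends, decomposition, and apparent migration

Crossing census years with sea-level years gives a matrix whose cell
$(c, s)$ is the population of census $c$ inside the zone delineated for
the sea level of year $s$. The change from $y_0$ to $y_1$ decomposes,
anchored at the terminal year:

* demographic component: $\mathrm{cell}(y_1, y_1) - \mathrm{cell}(y_0, y_1)$
  (same zone, censuses differ);
* sea-level component: $\mathrm{cell}(y_1, y_1) - \mathrm{cell}(y_1, y_0)$
  (same census, zones differ);
* the remainder $\mathrm{actual} - \mathrm{census} - \mathrm{sea}$ is
  reported as an explicit cross-term rather than silently absorbed.

County *apparent migration* is the per-county change in population inside
one fixed zone (the terminal-year sea level) across censuses — "apparent"
because an excess of deaths over births is indistinguishable from moves
in census data. The national apparent-emigration figure sums period
changes over the counties where that change is negative; counties where
the loss exceeds 1% of county population are flagged. Each subgroup's
national figure sums over the counties where *that subgroup's* change is
negative, so the subgroup figures are not constrained to add up to the
total — the published tables behave the same way.

## Disparity ratios

Two disproportionality measures are computed, deliberately both:

* **Nationwide ratio** — the subgroup's share of the zone population over
  its share of the reference population. A value of 1.63 reads: members
  of the subgroup are 63% more likely than the general population to live
  in the zone. It conflates two things: who lives in hazardous counties,
  and who lives on the hazardous land within them.
* **County-weighted ratio** — observed subgroup zone total over the total
  expected if, within every county, subgroup presence in the zone were
  proportional to the subgroup's county share. This filters out the
  between-county composition effect and isolates within-county sorting
  onto low ground. It is exactly 1 under within-county proportionality (a
  tested identity) and equals an inverse weighted harmonic mean of
  county-specific ratios.

The same expected-counts construction applies to emigration magnitudes
(`emigration_disparity()`) and to categorical overlays such as historical
mortgage-risk grades (`overlay_disparity()`).

## Numerical and interface choices

* Estimates are kept as reals throughout; rounding happens only at report
  time. Interpolated fractions of integer counts are not integers, and
  premature rounding breaks the additivity identities the tests rely on.
* Zone membership, block membership, and building membership all use the
  same half-open, cell-center conventions, so the composition of
  operations is exact: no sliver cells, no double counting.
* All randomness flows from one integer seed through deterministic
  sub-seeds per operation (`seed`, operation label, index), so regenerating
  any bundle is bit-identical and adding a new random stage does not
  perturb existing ones.
* Thresholds are compared strictly (`rel < z`): a cell at exactly the
  threshold is not "below" it. The choice is arbitrary but frozen and
  tested.
* Open questions resolved here, recorded for transparency: subgroup
  fractions inherit the block's total fraction (no finer model);
  zero-building partial blocks fall back to the area fraction rather than
  dropping out; blocks with no dry land get fraction 0 with a warning;
  floodplain polygons falling entirely off the grid classify inland with
  a warning rather than erroring, since mapped products routinely overhang
  the study area.

## Limitations

The package estimates *residence* exposure, not risk: it says nothing
about protection (levees and dikes can be modeled only as special
sampling strata), flood dynamics, or future development. Apparent
migration is an accounting identity on census counts, not a causal
estimate of climate-driven moves. The synthetic generator supports
validation of the arithmetic; it is not a forecast of any real coast, and
conclusions about method rankings transfer to real data only insofar as
the generator's core realism assumption — that buildings, and hence
people, avoid the lowest land within blocks — holds there.
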