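---
title: "Simulating urban greening scenarios and their heat mitigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating urban greening scenarios and their heat mitigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopycool)
```

## The problem

Urban tree canopy is among the most effective levers for reducing night-time
urban heat, but the benefit of planting depends not only on *how much*
canopy is added but on *where*. `canopycool` implements a spatially explicit
scenario pipeline for exploring that question at the agglomeration scale:
it identifies where the existing urban fabric permits new canopy, generates
stochastic greening scenarios under different spatial allocation strategies,
simulates the resulting air-temperature field with a biophysical cooling
model, and quantifies both the landscape pattern of the canopy and the
population exposed to high temperatures.

Because agglomeration-scale cadastral, orthoimagery and census inputs are
proprietary or bulky, the package also ships a synthetic-city generator that
produces all required inputs with the statistical structure the analysis
assumes. Every empirical statement in this vignette is computed by the test
suite or by `scripts/acceptance.R`; none is copied from external data.

## From land cover to refined classes

The pipeline starts from a 10 m integer land-use/land-cover (LULC) raster
and two 1 m binary masks (tree canopy, buildings). For every 10 m pixel the
masks give a tree-cover and a building-cover fraction
(`cover_fractions()`, the arithmetic mean of the 100 fine cells). Each
fraction is binned into four equal intervals — 0–25, 25–50, 50–75 and
75–100% — and the pixel's class is refined to the triple
*(base class, tree bin, building bin)*, encoded losslessly as
`base * 100 + tree_bin * 10 + building_bin`.

Two conventions matter here and are applied consistently throughout:

* **Bins are half-open below, closed at the top**: `[0, 0.25)`, …,
  `[0.75, 1]`. A pixel with exactly 75% tree cover is therefore *high
  canopy* (bin 3). Using one threshold for both the bin edge and the
  high-canopy rule avoids an off-by-one class between the refinement, the
  candidate rule and the landscape metrics.
* **High canopy means tree bin 3** (cover ≥ 75%). This corresponds to
  trees with a roughly 5 m crown radius spaced about 10 m apart, i.e. a
  closed canopy; adjacent high-canopy pixels form a continuous canopy
  patch.

The biophysical coefficients of a refined class derive from a per-base-class
table (`base_biophysical()`, shipped as CSV so it is configuration, not
code): the *shade* coefficient is the tree-bin midpoint (0.125, 0.375,
0.625, 0.875); the *albedo* is linearly interpolated between the base-class
albedo and the albedo of full building cover using the building-bin
midpoint; the crop coefficient `kc` and the green-area flag are inherited
from the base class. The interpolation endpoints (base-class albedo to
building albedo) are this package's reading of "interpolate by building
cover"; they bound the result by the two endpoint albedos by construction.
The shipped base values are role-consistent defaults for a temperate
European city (vegetated classes have high `kc`; dry impervious classes
zero; forest, garden and water carry the green-area flag); users with a
calibrated table should replace them.

## Candidate pixels and allocation strategies

A pixel qualifies for canopy increase when the urban fabric plausibly
permits a closed tree canopy over it:

1. its base class is one of *building, road/path, sidewalk, traffic
   island, other impervious, garden*;
2. its building cover is under 25% (building bin 0), leaving room for a
   crown;
3. road/path pixels must touch at least one pixel of a different class in
   their Moore (8-cell) neighbourhood — this excludes mid-road pixels such
   as highway interiors;
4. it is not already high canopy (transformation must change it).

Scenarios transform a proportion *p* of the candidates to the code with the
same base class and building bin but tree bin 3. Three allocation
strategies are provided. *Random* samples uniformly without replacement.
*Cluster* repeatedly transforms the candidate with the most high-canopy
pixels in its Moore neighbourhood; *scatter* the one with the fewest. Ties
are broken uniformly at random with the run seed, so a run is a pure
function of its configuration.

Two design choices were genuinely open:

* **Dynamic neighbour counts.** A transformed pixel immediately counts as
  high canopy for its neighbours' scores. The clustering strategy is meant
  to *grow* contiguous canopy; with static (precomputed) counts it would
  instead scatter around pre-existing canopy once the initially adjacent
  candidates were exhausted. Static counts remain available
  (`candidate_order(..., dynamic = FALSE)`) for comparison. The dynamic
  update is implemented in C++ with count buckets and lazy deletion, so a
  full ordering of tens of thousands of candidates takes milliseconds.
* **One ordering per run, truncated per proportion.** Each (strategy, run)
  pair derives one seed and one complete candidate ordering; the scenario
  at proportion *p* is its first `round(p * n)` entries (half-up rounding,
  so counts are exactly reproducible). Scenarios at increasing proportions
  within a run are therefore nested, which makes per-run temperature and
  exposure responses exactly monotone and removes a large source of
  sampling noise from the proportion effect. At *p = 1* every strategy and
  seed yields the same (full) set.

## The cooling model

Air temperature at the reference hour is simulated in four steps.

1. **Cooling capacity.** Each pixel's capacity is the weighted sum
   `CC = w_s * shade + w_a * albedo + w_e * ETI`, with
   `ETI = kc * ET0 / ET_max` clipped to `[0, 1]`. Default weights are
   (0.6, 0.2, 0.2) — shade dominates, matching the defaults of the widely
   used ecosystem-service cooling model this module reimplements. `ET0`
   can be a scalar, a matching raster, or a coarser raster (bilinearly
   resampled); `ET_max` defaults to the raster maximum. The Hargreaves
   formula (`hargreaves_et0()`) estimates `ET0` from daily
   minimum/average/maximum temperature when no raster is available.
2. **Park effect.** Green-flagged pixels form 8-connected patches; patches
   of at least `green_area_min` (default 2 ha) cool their surroundings
   within `d_cool` (default 100 m). Where that applies, the
   heat-mitigation index is `HM = max(CC, gam)`, with `gam` the
   distance-weighted mean of the green pixels' CC using weights
   `exp(-d / d_cool)` truncated at `d_cool`. The kernel is exact (tested
   against an all-pairs brute force at 1e-9), and because the green-area
   flag depends only on the base class, the patch set and kernel
   denominator are precomputed once per experiment.
3. **Temperature.** `T_nomix = T_ref + (1 - HM) * UHI_max`, where `T_ref`
   is the rural reference temperature and `UHI_max` the heat-island
   magnitude at the reference hour (21.00, the moment of maximal
   heat-island intensity). `select_reference_day()` derives both from a
   station series: among days whose coolest station exceeds 20 °C, the day
   with the largest max–min station spread; `T_ref` is the minimum and
   `UHI_max` the spread. The defaults (20.60 °C, 7.48 °C) correspond to
   such a peak heatwave evening.
4. **Air mixing.** `T_nomix` is blended with a Gaussian moving average of
   radius `r_mix` (default 500 m), implemented separably with
   `sigma = r_mix / 3`, truncated at three sigma and renormalized at the
   raster border (each 1-D operator's rows sum to one, which is exactly
   the border-renormalized 2-D kernel). Blending is convex, so
   `T_ref <= T_air <= T_ref + UHI_max` holds pixel-wise by construction.

The calibrated weights and distances of any particular study area are not
built in; all of (`cc_weights`, `d_cool`, `r_mix`, `green_area_min`,
`et_max`) are `climate_params()` configuration.

## Landscape metrics and exposure

Canopy pattern is quantified over the 8-connected patches of high-canopy
pixels (8-connectivity matches the Moore neighbourhood used in sampling;
4-connectivity is available): PLAND (percent of landscape), AREA_MN (mean
patch area, ha), SHAPE_MN (mean of `0.25 * perimeter / sqrt(area)`; the
common raster approximation, 1 for a single square cell) and ED (total
edge length per landscape area, m/ha). Patch perimeters count edges against
non-patch cells *and*, by default, the raster boundary; reference tools
differ on the boundary convention, so it is explicit
(`count_boundary = FALSE` for the interior-only variant). All four metrics
are verified against an independent brute-force edge/area counter on random
rasters at 1e-9.

Exposure couples the 10 m temperature field with a 100 m population grid:
each population cell receives the mean (optionally the maximum) of the
temperature pixels it covers, and the exposed count above a threshold sums
the population of cells *strictly* above it. Attribution is whole-cell
because the census is only resolved at 100 m.

## The synthetic city

`synth_city()` generates all inputs from a `city_blueprint()`: a concentric
layout (building-dense core, garden-rich residential ring, forest
periphery, water along the western edge), a connected road grid with one
three-cell-wide highway band (so the mid-road exclusion rule is exercised),
sidewalks and traffic islands attached to roads, a multinomial population
placed on building cells only, and a station series spanning an urbanity
gradient. Masks are built from class-conditional targets: buildings as
rectangles covering most of each building cell, trees as pseudo-disks
(crown radius ≈ 5 m at high densities) clipped to their 10 m cell and
trimmed so each cell's realized cover matches its jittered class target
(jitter SD 0.10, so refined tree bins vary within a class and some garden
pixels are already high canopy — the seeds the clustering strategy needs).

Default conditions: 2 500 m side (250×250 coarse cells — the extent must
tile into 100 m population cells, which is why the default is 2 500 rather
than a power of two), 50 000 inhabitants, class mix 5% water / 22% forest /
27% garden / 15% building / 11% road / 8% sidewalk / 2% traffic island /
10% other impervious — a plausible mid-size European agglomeration with
about 36 000 candidate pixels. Realized class fractions track the mix
within ±5 percentage points and realized cover densities match their class
targets within 0.1 mean absolute error (both tested).

What the generator does *not* emulate: real street topology, correlated
building/vegetation textures across cells, terrain and water-body
microclimates, and census heterogeneity beyond building density. Passing
tests on the synthetic city therefore demonstrate that the pipeline's
mechanics and orderings behave as designed, not that any particular real
agglomeration would show the same magnitudes.

## The experiment

`experiment_design()` defaults to 7 proportions (12.5% … 87.5%) × 3
strategies × 10 runs plus the single deterministic 100% scenario — 211
scenarios. Per-run seeds are derived from the master seed and the
(strategy, run) pair, so any single scenario can be re-run in isolation;
the whole experiment is a pure function of (inputs, design). Failed
configurations would be the caller's to handle; all stages validate their
inputs eagerly. `run_experiment()` returns per-scenario results (mean,
minimum and maximum temperature, maximum heat mitigation relative to the
baseline, the four metrics, per-class transformation tallies), a long
exposure table, per-proportion aggregate maps (mean temperature and heat
mitigation, modal LULC — exact because each pixel has only two possible
codes), and the baseline. `confidence_interval()` (Student-t) and
`strategy_contrast()` (difference of run means with Welch intervals)
support the standard summaries.

On the default synthetic city with master seed 42 the suite verifies the
qualitative behaviour expected of the mechanism: temperatures stay within
`[T_ref, T_ref + UHI_max]`; mean temperature decreases monotonically in the
proportion transformed for every strategy and run and is approximately
linear in the proportion (straight-line R² ≥ 0.95); at p = 0.25 clustering
yields larger mean patch area, lower edge density and a warmer mean
temperature than scattering; and the population exposed above the top
threshold orders scatter ≤ random ≤ cluster.

## Problem sizes and numerical choices

The test suite exercises unit behaviour on 30–50 cell grids and hand-built
toys, the brute-force oracles on ≤ 20×20 grids, and the full 211-scenario
experiment on the 250×250 default city (about two minutes on one core;
one simulation is dominated by the park-effect kernel, ~300 offset shifts
of the full grid). Other numerics: half-up rounding for selection counts;
ties in greedy sampling broken uniformly at random under the run seed;
Moore neighbourhoods at the border use in-bounds cells only (no wraparound
or padding); zero-patch landscapes report `NA` means (not 0); a proportion
that rounds to zero pixels returns an empty scenario with a warning.

## Limitations

The cooling model ignores building shade, three-dimensional canyon
effects and non-uniform air mixing; its response to canopy is close to
linear by construction, so threshold behaviour in exposure comes from the
population distribution, not from the physics. The biophysical defaults
are stand-ins, not calibrated values. The synthetic city is a statistical
emulation; conclusions about a real agglomeration require its actual
rasters and a locally calibrated parameter set.
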