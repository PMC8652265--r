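# canopycool

Spatially explicit simulation of urban tree-canopy greening scenarios and
their night-time heat-mitigation potential, with population heat-exposure
accounting — for landscape ecologists, urban climate researchers and
planners who want to compare *where* to add canopy, not just *how much*.

## What it does

Starting from a 10 m land-use/land-cover (LULC) raster and 1 m binary
tree-canopy and building masks, the package:

1. **refines** every LULC pixel by its tree- and building-cover fractions,
   binned into four equal intervals (a pixel with cover ≥ 75% is *high
   canopy*); refined class *(c, t, b)* gets shade coefficient equal to the
   tree-bin midpoint (0.125/0.375/0.625/0.875) and an albedo interpolated
   towards the building albedo by the building-bin midpoint;
2. **maps candidate pixels** where canopy can realistically be added: base
   class in {building, road/path, sidewalk, traffic island, other
   impervious, garden}, building cover < 25%, road pixels only when they
   touch another class, and not already high canopy;
3. **generates scenarios** transforming a proportion *p* of candidates to
   their high-canopy class under three allocation strategies — uniform
   *random*, *cluster* (greedily pick the candidate with the most
   high-canopy Moore neighbours, dynamically updated) and *scatter* (the
   fewest) — with seeded, nested, fully reproducible sampling;
4. **simulates air temperature** with a cooling-capacity model,
   `CC = 0.6·shade + 0.2·albedo + 0.2·ETI` (weights configurable),
   a park effect for green patches ≥ 2 ha (exponential distance decay
   within 100 m) and Gaussian air mixing (500 m radius), mapping
   `T = T_ref + (1 − HM)·UHI_max`;
5. **quantifies** the canopy pattern with PLAND, AREA_MN, SHAPE_MN and ED
   over 8-connected high-canopy patches, and the **population exposed**
   above temperature thresholds on a 100 m census grid.

A synthetic-city generator (`synth_city()`) emulates a rasterized urban
fabric — concentric building/garden/forest rings, a connected road grid, a
building-weighted population surface and a station temperature series — so
the full pipeline runs and is tested without any external data. The
default experiment is 7 proportions × 3 strategies × 10 runs + the
deterministic 100% scenario = 211 simulations.

## Worked example

```r
library(canopycool)

city    <- synth_city(city_blueprint(side_m = 1000, pop_total = 8000, seed = 1))
refined <- refine_lulc(city$lulc,
                       cover_fractions(city$tree_mask, 10),
                       cover_fractions(city$building_mask, 10))
refined
#> <refined_lulc> 100 x 100 cells at 10 m, 18 refined classes
#> base classes: building=1500, forest=2200, garden=2462, other_impervious=1000,
#>   road_path=1338, sidewalk=800, traffic_island=200, water=500

rd <- select_reference_day(city$stations)   # hottest admissible evening
params <- climate_params(t_ref = rd$t_ref, uhi_max = rd$uhi_max)

ex <- run_experiment(refined, population = city$population, params = params,
                     design = experiment_design(
                       proportions = c(0.25, 0.5, 0.75),
                       runs_per_config = 5, master_seed = 42),
                     et0 = 5)
ex
#> <greening_experiment> 46 scenarios, 5700 candidate pixels
#> mean T over scenarios: 25.208 to 26.151 degC

aggregate(cbind(t_bar, area_mn, ed) ~ proportion + strategy,
          data = ex$results, mean)
#>    proportion strategy t_bar  area_mn    ed
#> 1        0.25  cluster 26.15  4.95956 129.8
#> 2        0.50  cluster 25.89 10.54733 128.1
#> 3        0.75  cluster 25.61 31.46500 130.7
#> 4        1.00     full 25.21 77.18000 235.6
#> 5        0.25   random 26.08  0.09043 557.8
#> ...
```

Reading the numbers: greening 25–75% of the 5 700 candidate pixels lowers
the mean simulated 21.00 air temperature from 26.15 to 25.43–25.61 °C
depending on strategy; clustering builds patches two orders of magnitude
larger (AREA_MN) with far less edge (ED) than scattering, but stays
consistently *warmer* — and it leaves more people exposed to the hottest
temperatures:

```r
e26 <- ex$exposure[ex$exposure$threshold_c == 26, ]
aggregate(exposed_count ~ proportion + strategy, data = e26, mean)
#>    proportion strategy exposed_count
#> 1        0.25  cluster        7994.4
#> 2        0.50  cluster        7982.2
#> 3        0.75  cluster        7881.6
#> 4        1.00     full        4912.0
#> ...
#> 8        0.25  scatter        8000.0
#> 9        0.50  scatter        7993.0
#> 10       0.75  scatter        6793.0
```

At 75% transformation, scattering leaves ~6 800 of 8 000 inhabitants above
26 °C versus ~7 900 for clustering: spatial configuration matters most at
the extremes of the temperature distribution. `strategy_contrast()` returns
these differences with 95% confidence intervals across runs.

See `vignettes/urban-greening-methods.Rmd` for the model, its assumptions,
parameter defaults and the design decisions behind the samplers, metrics
and exposure conventions.

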