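# treelineq

Driver attribution for alpine treeline expansion with the
stratified-heterogeneity *q* statistic.

## The problem

Alpine treelines are advancing upslope under climate warming, but not
uniformly: how much of the observed expansion of a treeline species is
explained by temperature, how much by precipitation, and how much by the
terrain that redistributes both (aspect, relief, soil moisture)? And do
pairs of factors act together more strongly than either alone?

`treelineq` implements the full analysis chain a spatial ecologist needs to
answer these questions from raster data:

* **Terrain factors** from a DEM: Horn slope, aspect, neighbourhood relief,
  D8 flow accumulation and the topographic wetness index
  TWI = ln(α / tan β), plus a seven-class slope taxonomy and
  summit-azimuth aspect sectors.
* **Climate factors**: statistical downscaling of coarse monthly climate by
  multiple linear regression on elevation, slope and (sin, cos) aspect;
  seasonal aggregates (growing-season precipitation and temperature,
  coldest/warmest-month variables); correlation pruning at |r| > 0.90.
* **Cover mapping**: spectral indices (NDVI, NDWI, soil NDSI), field-sample
  filtering and stratified 70/30 splitting, a pluggable binary classifier
  (radial-kernel SVM by default) and accuracy assessment.
* **Change analysis**: two-date change maps, annual expansion rates,
  per-sector area/elevation summaries, slope-class distributions, and the
  density-increase response surface (percent of each analysis cell that
  switched from absent to present).
* **Geodetector**: the factor detector and interaction detector built on
  the stratified-heterogeneity statistic

  q = 1 − SSW/SST,  SSW = Σ<sub>h</sub> N<sub>h</sub> σ<sub>h</sub>²,  SST = N σ²

  with population variances, overlay (Cartesian-product) strata for
  factor pairs, and the five-way interaction taxonomy (nonlinear
  enhancement, dual-factor enhancement, independence, weakening).
* **A synthetic landscape generator** — volcano-shaped DEM, lapse-rate
  climate, and an expansion-only presence series whose colonization
  probability is a known logistic function of chosen factors — so the whole
  pipeline is testable end to end with known ground truth.

Rasters are carried in a light `raster_grid` container and exchanged on
disk as plain-text ESRI ASCII grids; tables are CSV; configuration is YAML.

## Worked example

```r
library(treelineq)

## the q statistic on a toy response: two well-separated strata
factor_q(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 2, 2, 2))
#> q = 0.96813 (N = 6, 2 strata)
# SSW = 4.0, SST = 125.5: the stratification explains 96.8 % of the variance

## a synthetic 100x100 scene, end to end
truth <- synthetic_truth(seed = 42, nrow = 100, ncol = 100)
scene <- simulate_scene(truth)
ch <- change_map(scene$series, 2002, 2021)
attr(ch, "areas_hm2")
#> absent_stable     unchanged      expanded       reduced
#>        1399.5         875.0         225.5           0.0
annual_rate(875, 875 + 225.5, year_span(2002, 2021, "inclusive"))
#> [1] 1.288571    # percent per year over the 20-year (inclusive) span

resp <- as_response_table(density_increase(ch, 10))
det <- run_detectors(resp, scene$factors, k = 5)
head(det$factor_q, 3)
#>   sector    factor          q   N
#> 1    all elevation 0.55749484 100
#> 2    all   T_MEAN8 0.11496458 100
#> 3    all       TWI 0.07535711 100
head(det$interaction_q, 2)
#>   sector factor_a  factor_b         qA        qB       qAB          category  N
#> 1    all    Pre_8 elevation 0.02581494 0.5537835 0.6621725 nonlinear-enhance 98
#> 2    all    Pre_1 elevation 0.02649407 0.5556615 0.6559987 nonlinear-enhance 99
```

The factor table says elevation alone explains 56 % of the spatial variance
of the density increase on this scene; the interaction table shows pairs
whose overlay explains more than the sum of their parts (nonlinear
enhancement) — here precipitation × elevation pairs, reflecting that on an
unmasked scene the expansion front itself tracks elevation.

## The analysis workflow

The numbered scripts under `analysis/` reproduce the study chain on the
default synthetic scene and write their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | simulate the 200×200, 50 m volcano scene and cover series |
| `02_terrain.R` | slope/aspect/relief/TWI, slope classes, aspect sectors |
| `03_climate.R` | downscaling skill check, factor pruning at \|r\| > 0.90 |
| `04_change.R` | change map, expansion rates, sector/slope summaries, density response |
| `05_drivers.R` | factor and interaction detectors per sector, k-sensitivity sweep |
| `06_recovery.R` | planted-driver Monte-Carlo recovery experiments |

Run them in order from the repository root after installing the package.

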