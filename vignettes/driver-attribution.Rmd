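---
title: "Attributing treeline expansion to interacting drivers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing treeline expansion to interacting drivers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistic at its core, the raster processing around it, the synthetic
landscape that makes the whole chain testable, and the design decisions
taken where the methodology is genuinely open.

## The q statistic

The central quantity is the stratified-heterogeneity statistic

$$ q = 1 - \frac{\mathrm{SSW}}{\mathrm{SST}}, \qquad
   \mathrm{SSW} = \sum_{h=1}^{L} N_h \sigma_h^2, \qquad
   \mathrm{SST} = N \sigma^2 , $$

where the response $Y$ (here: the percentage of an analysis cell that
switched from species-absent to species-present between two dates) is
partitioned into $L$ strata by a discretized explanatory factor,
$N_h$ and $\sigma_h^2$ are the size and *population* variance of stratum
$h$, and $N$, $\sigma^2$ are the overall size and population variance.
$q$ is the fraction of the spatial variance of $Y$ removed by the
stratification: 0 when stratum means are all equal, 1 when $Y$ is constant
within every stratum. It makes no linearity or distributional assumption
about the factor–response relationship — only that whatever relationship
exists is expressible through the strata. Population (not sample)
variances are used throughout, which is what makes the identity
$\mathrm{SST} = \mathrm{SSW} + \mathrm{SSB}$ exact at any stratum size.

The *factor detector* is $q$ computed for one factor. The *interaction
detector* forms overlay strata — one stratum per distinct pair of labels
$(h_A, h_B)$ — and computes $q_{AB}$ on the overlay. Comparing
$q_{AB}$ with $q_A$, $q_B$ classifies the interaction:

| condition | category |
|---|---|
| $q_{AB} > q_A + q_B$ | nonlinear enhancement |
| $q_{AB} = q_A + q_B$ | independence |
| $q_{AB} > \max(q_A, q_B)$ | dual-factor (bi-) enhancement |
| $\min \le q_{AB} < \max$ | single-factor weakening |
| $q_{AB} < \min(q_A, q_B)$ | nonlinear weakening |

Sum comparisons are evaluated before max comparisons, with an absolute tie
tolerance of $10^{-9}$.

Three implementation decisions matter here and were genuinely open:

* **Same-sample overlay.** `interaction_q()` recomputes $q_A$ and $q_B$ on
  exactly the observations retained by the overlay (small overlay strata
  dropped first, then the single-factor values computed with
  `min_stratum_n = 1` on that same set). On a shared sample, refining a
  partition can never increase SSW, so $q_{AB} \ge \max(q_A, q_B)$ holds
  to machine precision — the two *weakening* categories are then
  mathematically unreachable. They remain implemented and classifiable
  (the taxonomy is exposed as `classify_interaction()` for externally
  computed triples) but cannot occur in this package's own workflow. Had
  each $q$ been computed on its own maximal sample, small-stratum drops
  could break the refinement inequality; we consider the same-sample
  convention the only one under which the taxonomy is internally
  consistent.
* **Boundary ties.** The taxonomy's verbal rules leave $q_{AB}$ exactly
  equal to $\max(q_A, q_B)$ unassigned (weakening requires strictly less,
  enhancement strictly more). Because refinement guarantees
  $q_{AB} \ge \max$, we resolve ties at the max (within tolerance) to
  *bi-enhance*; the degenerate case of overlaying a factor with a copy of
  itself therefore reports $q_{AB} = q_F$ with category bi-enhance.
* **Degenerate inputs.** A constant response has $\mathrm{SST} = 0$ and
  $q$ undefined: this is an error, not a 0 or 1. Strata with fewer than
  `min_stratum_n` observations (default 2, the minimum for a variance)
  are dropped and logged, never silently merged. Observations missing the
  response or any factor are excluded listwise.

No significance test is attached to $q$; the noncentral-F test of the
wider geodetector literature is a documented extension point.

### Discretization

The stratification of continuous factors is a free parameter of the
method, and published applications rarely state theirs. The default is
quantile (equal-frequency) binning with $k = 5$ strata — robust to skewed
factor distributions and the least informative choice. Equal-interval and
exact variance-minimising 1-D partitioning (Fisher–Jenks, by dynamic
programming over the sorted unique values, condensed onto at most 2000
quantile micro-bins for large inputs) are available, as is pass-through
for already-categorical factors. Because the choice is consequential and
conventional, `sweep_strata()` reports $q$ over $k = 3$–$8$ as a built-in
sensitivity analysis. If a factor has fewer distinct values than $k$, the
stratum count is reduced with a warning.

## Terrain factors

Slope and aspect use Horn's third-order finite differences on the 3×3
neighbourhood; the grid border is padded by linear extrapolation, which
reduces to one-sided differences and keeps planar surfaces exact to the
edge. Aspect is the azimuth of steepest descent (0° = north, clockwise);
cells with gradient magnitude below $10^{-6}$ m/m receive the flat
sentinel −1. Relief is the max − min elevation in an odd square window,
default 3×3 cells (150 m at 50 m resolution — no window is standard in
the literature; it is configurable).

The wetness index is $\mathrm{TWI} = \ln(\alpha / \tan\beta)$ with
$\alpha$ the specific catchment area from single-direction (D8) flow
routing: depressions are filled to their pour points with a tiny
monotonicity epsilon, every cell then routes to its steepest-descent
neighbour (ties broken by the fixed order E, SE, S, SW, W, NW, N, NE for
exact reproducibility), accumulation counts the cell itself, and
$\alpha$ is accumulated area divided by cell width. $\tan\beta$ is
floored at 0.001 so flat cells stay finite. Multiple-flow-direction
routing would diffuse $\alpha$ more realistically on divergent slopes but
is out of scope.

Slope classes follow the seven-class geomorphological taxonomy applied in
**degrees** (plain [0, 2), gentle ramp [2, 5), ramp [5, 15), steep
[15, 25), very steep [25, 35), scarp, vertical ≥ 55). The published class
list skips 45–55; the scarp class is extended to [35, 55) so that the
classes partition the full range — every valid cell gets exactly one
class.

Aspect sectors are assigned by the azimuth *from the summit to the cell*,
not by each cell's own aspect: a mountain's "northern slope" is a region,
and local aspect within it varies with every gully. Sector boundaries
default to 90° quadrants centred on the cardinal directions; any sector
can be masked out to mirror a study-area exclusion (the analysis scripts
mask the eastern sector). Per-cell aspect binning remains available by
classifying `compute_aspect()` output directly.

## Climate factors

Coarse monthly climate is downscaled by ordinary least squares on
elevation, slope and aspect, with aspect entering as the $(\sin, \cos)$
pair — a circular variable cannot enter a linear model raw, and the pair
is the minimal faithful encoding. The model is fitted over coarse cells
and predicted at fine cells; a rank-deficient design falls back to
elevation-only with a warning. Residuals are not interpolated back.
Downscaling skill is summarised as RMSE and $R^2 = 1 - SSE/SST$ against
held-out station values.

Derived factors follow the usual treeline set: growing-season
precipitation and mean temperature (season months default June–September,
the conventional northeast-Asian alpine growing season; configurable),
coldest-month (January) and warmest-month (August) precipitation, and
warmest-month mean temperature. The cold/warm months are fixed by
subscript rather than computed per cell, matching how such factors are
defined in practice. Candidate factors are then pruned: while any pair of
factors has |Pearson r| > 0.90 over the shared valid cells, the
lower-priority member of the worst pair is dropped (priority = input
order by default) and logged. On lapse-dominated synthetic scenes this
correctly collapses the temperature factors onto one representative.

## Cover mapping

The feature space is six reflectance bands plus NDVI, NDWI and a soil
index NDSI = (SWIR1 − NIR)/(SWIR1 + NIR) — the *soil* form, not the
snow index that shares the acronym; the choice is recorded in the output
metadata. Sample handling reproduces the field-survey ledger logic:
boundary filtering, visual-interpretation rejection, then a
stratified-by-class random split with half-up rounding of the total
training size (so 411 samples at 70 % give 288) allocated across classes
by largest remainder. The classifier is a contract — `fit(x, y)` and
`predict(model, x)` — defaulting to a radial-kernel soft-margin SVM from
e1071; the package deliberately does not reimplement the optimizer.
Object-based segmentation and the manual patch-refinement step of
operational workflows are out of scope; the degenerate cases (single
training class, identical feature vectors) error and warn respectively.

## Change analysis

Two-date change maps classify every cell as absent-stable, present-stable,
expanded or reduced; areas are reported in hm² (1 hm² = 10⁴ m²). The
annual expansion rate is the simple convention
$((A_2 - A_1)/A_1) \cdot 100 / \mathrm{span}$ — not compounded. The span
is configurable because the two defensible conventions disagree by one
year: calendar difference ($t_2 - t_1$) versus inclusive counting
($t_2 - t_1 + 1$, under which 2002–2021 spans 20 years). The replication
profile uses the inclusive span, which is the arithmetic under which a
24.26 % total increase over 2002–2021 yields 1.21 % a⁻¹.

The detector response is the density increase: the percentage of valid
fine cells within each aggregated analysis cell that switched 0 → 1.
Aggregation defaults to 10×10 fine cells (500 m analysis cells at 50 m
resolution); the recovery experiments use 5×5 (250 m) to resolve the
active colonization zone. Expansion-only enforcement (clamping reductions)
is available but off by default — nested input series simply produce an
empty reduced category.

## The synthetic landscape

The generator exists so that every downstream stage can be tested against
known truth without any external data. It emulates:

* a **volcano DEM**: a cone (summit 2600 m, gradient 0.10 m/m on a
  200×200-cell, 50 m grid) plus a Gaussian random field smoothed to a
  400 m correlation length with 15 m amplitude — enough roughness to give
  TWI and relief real structure while keeping the four aspect sectors
  intact;
* **lapse-rate climate**: monthly means affine in elevation at
  −0.0065 °C/m around a seasonal sea-level cycle, a ±0.5 °C south-facing
  aspect modulation, and spatially correlated noise (SD 0.3 °C, 500 m
  correlation length); precipitation with a monsoon-peaked monthly
  baseline, +0.03 mm/m elevation gradient and correlated noise, floored
  at zero. The amplitudes keep the scene inside the plausibility envelope
  of a cold temperate mountain massif;
* an **expansion-only presence series**: presence starts below the 0.35
  elevation quantile and spreads by neighbourhood colonization — an
  absent cell with an occupied neighbour within the Chebyshev radius
  (default 1 cell) colonizes each year with probability
  $\mathrm{logistic}(\beta_0 + \sum_i \beta_i z_i +
  \sum_{ij} \beta_{ij} z_i z_j) \times \mathrm{scale}$, where the $z$ are
  z-scored factor values (so that effect sizes are comparable across
  factors with different units). Presence never reverts. Annual updates
  run between the observation years 2002/2010/2017/2021.

What the generator does **not** emulate: seed dispersal kernels, age
structure and fecundity, snowpack process dynamics, classification error
in the cover maps, and spatial autocorrelation of the response beyond
what the colonization process itself induces. Passing recovery tests
therefore show that the detector chain identifies drivers *when the data
generating process matches the suitability model's form*; they do not
show robustness to misspecification on real imagery.

### Designing a recoverable experiment

A subtlety worth recording: under strictly contact-limited spread
(radius 1), *where* expansion occurs is dominated by *where the front
is*, and the front is an elevation contour — so the expansion surface
correlates overwhelmingly with elevation no matter which factor drives
the colonization probability. Two design elements of the recovery
experiments address this, both with real-world analogues:

* the detectors are run on the **treeline ecotone band** (analysis cells
  with mean elevation 2170–2450 m), mirroring how such studies bound
  their study area to the elevation belt where the process operates —
  below it the response is saturated, far above it unreachable, and
  either regime measures only the band position;
* colonization uses a **250 m dispersal radius (5 cells) at a low
  per-year scale (0.25)** over a rougher DEM (40 m amplitude, 750 m
  correlation length), so that reachability is broad and realized
  colonization is suitability-limited — a reasonable regime for a
  wind-dispersed birch at decadal timescales.

With TWI planted as the dominant factor (β = 2.5, all else zero) the
factor detector's top q must identify TWI; with a pure TWI × Pre_1
interaction planted (β = 3, no main effects) the interaction detector's
top pair must be (TWI, Pre_1) with category nonlinear-enhance. Both are
run as 20 seeded 200×200 replicates with a ≥ 90 % hit-rate criterion
(`run_recovery_experiments()`; `analysis/06_recovery.R`).

## Problem sizes and numerical tolerances

The test suite exercises: exact-arithmetic checks in well under a second;
brute-force oracle equivalence of `factor_q`/`interaction_q` at
$10^{-12}$ over 100 random instances up to $n = 10^4$; D8 accumulation
against exhaustive upstream traversal on grids up to 12×12 (exact
equality); the null calibration $E[q] \approx (L-1)/(N-1)$ by 500
Monte-Carlo replicates at $N = 2000$, $L = 5$, within three standard
errors; lapse-rate recovery at 400 coarse cells within ±0.0005 of
−0.0065; and the two recovery experiments at 20 replicates each. These
sizes were chosen to bound every stochastic check well away from its
threshold while keeping the full suite in the low minutes on one core.

## Known limitations

* D8 routing concentrates flow on convergent paths and underestimates
  $\alpha$ on divergent slopes; TWI values are conventional, not
  hydrologically calibrated.
* The q statistic ignores spatial autocorrelation; with strongly
  autocorrelated responses the effective sample size is smaller than N
  and q values are optimistic in absolute terms (rankings are less
  affected). No correction is applied, and no significance test is
  reported.
* Exact q values depend on the stratification (method and k); only
  sensitivity sweeps, not a canonical choice, are provided.
* The downscaling regression assumes the coarse-scale
  climate–topography relationship transfers to the fine scale, and adds
  no residual field.
* The pipeline's cover-mapping stage is validated on synthetic features;
  no radiometric preprocessing of real imagery is included.
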