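---
title: "Methods: multiscale habitat models and resistant-kernel connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale habitat models and resistant-kernel connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelscape)
```

## The analysis

kernelscape implements a complete habitat-to-connectivity pipeline for a
territorial, habitat-specialist mammal on a gridded montane landscape:

1. occurrence preparation (spatial thinning, constrained pseudo-absences),
2. a multiscale covariate stack (focal means, FRAGSTATS-style
   moving-window metrics, distances, densities),
3. a two-step equal-sampling multiscale random-forest habitat model,
4. an exponential suitability-to-resistance transform,
5. resistant-kernel and factorial least-cost-path connectivity,
6. core-habitat extraction and protected-area accounting.

Because real survey occurrences for such species are rarely public, the
package ships a seeded synthetic-landscape generator whose suitability
surface is *known by construction*; every stage of the pipeline is
validated by recovering the generator's parameters (effect scales, the
elevation optimum, class separability) rather than by comparison to an
irreproducible data set.

## Occurrence preparation

**Thinning.** The thinning rule is greedy: while any pair of points is
closer than the radius (default 1,200 m, the scale of an average home
range), remove the point with the most neighbors within the radius,
breaking ties by removing the lowest point index. The result is maximal
(no removed point could be restored) and deterministic; thinning is
idempotent. The tie rule is a documented implementation choice — the
commonly used GIS toolboxes do not publish theirs.

**Pseudo-absences.** Ten sets, each exactly as large as the presence
set (random forests are sensitive to class imbalance, so every fitted
dataset is balanced 1:1). Eligibility is evaluated on cell centers:
outside a 3,000-m buffer around every presence, below 4,000 m elevation
and 50° slope. Points are rejection-sampled over eligible cells with a
uniform jitter inside the cell, a post-jitter re-check of the presence
buffer, and a sequential 1,200-m within-set spacing constraint (earlier
accepted points constrain later ones). Sampling failure after
10,000 × n attempts raises an error naming the binding constraint.

## Covariate engine

The vocabulary has 16 window-scalable variables — focal means of
elevation, slope position, transformed aspect, ruggedness, productivity
and bamboo; landscape-level AI, ED, PD, SHDI; class-level LPI and PLAND
for the two closed-forest classes; village and road densities — plus 3
unscaled distance layers, at radii 1,000–6,000 m.

Conventions, all chosen to match FRAGSTATS moving-window behavior where
the metric names come from:

* windows are **circular** (cell centers within the radius), truncated
  at the raster edge, and metrics are computed over valid cells only;
* patches are 8-connected and clipped to the window;
* PD is reported per 100 ha and ED in m/ha, so magnitudes are comparable
  to the landscape-ecology literature;
* AI is the proportion-weighted like-adjacency ratio with single-count
  rook adjacencies and the standard maximum-adjacency formula;
  single-cell classes contribute zero;
* aspect is transformed as TRASP = (1 − cos(π/180 · (aspect − 30)))/2,
  with flat cells assigned the neutral 0.5;
* slope position is elevation minus the focal-mean elevation (a TPI),
  by default within 750 m;
* feature densities divide the windowed count (or chopped-segment road
  length) by the geometric window area πr²; distance layers are exact
  point/segment distances from cell centers.

The moving-window metrics are implemented in C++ (per-window flood fill
for patch metrics); they are tested cell-by-cell against brute-force
double-loop references and hand-computed fixtures.

## Two-step multiscale random forest

**Step 1 — scale optimization.** For each variable and each candidate
scale, a univariate 500-tree forest is fitted to every balanced dataset
and its OOB misclassification recorded. Per dataset, the scale with the
lowest OOB error wins (ties to the finest scale — conservative toward
home-range-level selection); the final scale is the mode across the ten
datasets (ties again to the finest). 500 trees are used in all models,
including the univariate ones.

**Collinearity screen.** Pairs of chosen-scale layers with |Pearson r| >
0.85 over valid cells lose one member; the member with the higher mean
univariate OOB error (the less predictive one) is dropped. Constant
layers have undefined correlation and are retained with a warning.

**Step 2 — MIR selection.** Each dataset's full forest is fitted with
permutation importance. MIR standardizes importances to [0, 1] by
dividing by the maximum; negative permutation importances are clamped to
zero first, so the 0.0 threshold always reproduces the full model.
Subsets at thresholds 0, 0.1, …, 0.9 are always formed from the
*original* model's importances (no iterative re-ranking, which
over-fits); each non-empty subset is refitted and the lowest-OOB subset
kept, ties to the smaller subset. A dataset in which no variable attains
positive importance is a degenerate fit and raises an error. The final
per-dataset model is a probability forest on the selected subset;
ensemble suitability HS is the across-model mean of the per-cell
presence vote fraction, in [0, 1], with nodata propagated from any
required covariate.

**Evaluation.** AUC is rank-based (midranks, so ties count one half) —
the probability that a random presence outscores a random
pseudo-absence. Data are split 70/30 stratified by class; models are
*refitted* on the training part (an interpretation choice: the
evaluation measures the procedure, not one frozen fit) and scored on the
validation part; ten repetitions give the mean and SD. Single-class
validation folds are redrawn and counted.

**Partial dependence** fixes all other variables at each member's
training mean, varies the target over its observed range, and reports
the ensemble mean with a 95% band across members.

## Resistance transform

The exponential form `raw = 1000^(−HS)` is rescaled linearly from
[1000⁻¹, 1] onto [1, 100], so R(1) = 1 and R(0) = 100 exactly, R is
strictly decreasing and convex, and R < 10 for all HS > 0.44 — most of
the landscape receives low resistance, only clearly unsuitable cells
resist movement strongly. Inputs outside [0, 1] are an error; nodata
propagates.

## Connectivity engines

The cost graph connects valid cells to their 8 neighbors with weight
(mean of the two resistances) × (center distance, with √2 on
diagonals). With uniform R = 1 an edge weight equals its geometric
length, which *calibrates the cost unit*: 1 cost unit = 1 m traversed at
minimal resistance. Shortest paths and accumulated costs use Dijkstra's
algorithm (via igraph on this explicit graph); equal-cost path ties are
broken by the library's deterministic internal ordering, so outputs are
reproducible run-to-run.

**Resistant kernels** decay linearly with accumulated cost,
k = max(0, 1 − cost/θ) (a Gaussian option is available), and are summed
over sources; an isolated source cell scores exactly 1. Support is
monotone in θ, and on uniform resistance the support is a disc of radius
θ within one cell (the 8-neighbor metric overestimates off-axis
distances by at most ≈ 8%, under a cell at the default thresholds-to-
resolution ratio used in the tests).

**Factorial least-cost paths** connect all unordered source pairs with
path cost ≤ 50,000 cost units. Each path is rasterized as a unit
indicator over its cells and convolved with a unit-sum 2-D Gaussian
(default σ = 2 cells = 500 m; none is prescribed by the corridor
literature, and σ is exposed). The unit-sum kernel preserves each path's
mass away from the raster edge, and pixel values count the paths running
through the pixel's neighborhood; with σ → 0 the support is exactly the
union of raw path cells.

## Core habitats and protection

Core habitat keeps cells *strictly greater* than 5% of the kernel-surface
maximum ("greater than" is read literally; the ≥ variant differs only on
ties) and labels maximal 8-connected patches. A cell is protected iff
its center lies inside a protected-area polygon — the same center-based
convention as the windows. Reports carry unrounded percentages plus a
whole-percent view, since protection tables are conventionally printed
in whole percent.

## The synthetic landscape

The generator emulates, at 250-m resolution in projected meters
(north-up, cell-center registration):

* **Terrain**: a spectrally filtered Gaussian random field with a
  two-component spectrum — a regional component (correlation length 20
  cells = 5 km; massifs and valleys) plus 35% of variance at 3 cells
  (ridge-and-gully detail) — standardized to an amplitude of 900 m
  around a 2,200-m base and clamped to 500–5,000 m. The detail component
  is what makes 1-km focal means informative beyond 2-km ones.
* **Bamboo**: Bernoulli presence with probability peaked inside the
  2,000–3,200 m elevation band and modulated by a smooth
  stand-patchiness field (correlation 3 cells), then 3×3
  majority-smoothed. Stands are contiguous but fine-grained, so the
  1-km window genuinely carries more signal than coarser ones.
* **Settlement**: villages agglomerate into compact settlements
  (≈ 6 villages within 300 m of each center), centers drawn with a
  low-elevation bias under a 7-km inhibition distance. This geometry is
  what makes the 4-km density scale identifiable: a 4-km window sees a
  given settlement from a presence-feasible distance either fully or not
  at all, whereas a 6-km window cannot distinguish a settlement 1 km
  away from one 5 km away, and a 2-km window misses the settlements
  that actually suppress habitat.
* **True suitability**: logistic in three terms — a unimodal elevation
  effect (optimum 2,600 m, width 300 m) at the 1-km scale, a positive
  bamboo effect at 1 km, and a negative village-density effect
  (−40 per village/km²) at 4 km — fine-scale biotic selection versus
  coarse-scale anthropogenic avoidance. Generative terms use exactly
  the same windowed quantities (focal means, feature densities) as the
  covariate engine, so scale recovery is a fair test rather than a
  normalization artifact.
* **Occurrences**: cells drawn without replacement with probability
  proportional to true suitability, jittered within the cell. The
  default density is 0.06 points/km² (≈ 150 points on the 200×200-cell
  reference landscape, ≈ 110 after thinning) — about twice the density
  of a mountain-range survey with 528 records over ~15,700 km². The
  choice balances two pressures on a 2,500-km² desk-scale landscape:
  balanced datasets large enough that OOB differences between adjacent
  scales exceed their sampling noise, and enough eligible area left
  outside the 3-km presence buffers for spaced pseudo-absences.

What the generator does **not** emulate: survey detection bias and
transect geometry, bamboo phenology and its remote-sensing estimation,
roads as movement barriers (roads enter covariates only), real
land-cover class mosaics, temporal change. Passing recovery tests
therefore show that the *procedure* identifies planted multiscale
structure under realistic spatial autocorrelation — not that any
particular real landscape satisfies the model's assumptions.

## Numerical conventions and degenerate inputs

* All randomness flows from explicit integer seeds; generators restore
  the caller's RNG state. Identical configuration + seed ⇒ bit-identical
  outputs, including across the full pipeline (content checksums in the
  run manifest).
* Forests run single-threaded with fixed seeds (`ranger`), 500 trees
  default.
* Focal radii below half a cell warn and return the input; empty
  feature sets are an error for distances (undefined) but a zero
  surface for densities; an all-zero kernel surface yields an empty
  patch set; an empty protected-area set reports 0% with a warning.
* Cost-distance oracle equivalence is asserted at 1e−9; the resistance
  endpoints at 1e−9; window metrics exactly against hand-computed
  fixtures.
* Test problem sizes: scale recovery uses five 200×200-cell landscapes
  (the reference study condition); connectivity monotonicity a 150×150
  landscape; the pipeline smoke tests 100×100 with reduced scale and
  tree counts. These sizes keep the full suite around two minutes while
  leaving every stage's logic identical to a production run.

## Design decisions on genuinely open points

* **Univariate forests use 500 trees**, like every other forest here;
  tree-count floors found by OOB stabilization curves elsewhere do not
  justify a special case ("500 in all models" is taken literally).
* **AUC refits per split** rather than scoring the frozen ensemble, as
  discussed above.
* **Core cutoff is strict** (> 5% of maximum).
* **Collinear drops keep the more predictive member**, ranked by mean
  univariate OOB error at the chosen scale.
* **Window shape is circular** with edge truncation; square windows
  would distort radii-based scale labels.
* **Per-path corridor mass is the path's cell count** (unit indicator,
  unit-sum blur); normalizing every path to total mass 1 would instead
  down-weight long corridors, which is not how path-frequency maps are
  read.

## Limitations

Suitability is a home-range-selection quantity and only a proxy for
dispersal resistance; the exponential transform encodes that assumption
but cannot repair it. The equal-sampling ensemble calibrates vote
fractions only relatively (they are not occurrence probabilities). The
8-neighbor graph metric inflates off-axis distances by up to ~8%, which
matters for kernel isotropy at coarse thresholds on fine grids. Window
metrics are exact but O(cells × window area); very large rasters with
6-km windows are the slow path of the stack builder.
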