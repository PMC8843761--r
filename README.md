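# kernelscape

Scale-optimized habitat modelling and landscape connectivity analysis on
gridded landscapes, built for the workflow used in montane wildlife
studies (the motivating case is a bamboo-specialist large mammal in a
fragmented mountain range): map habitat suitability with a multiscale
random-forest species distribution model, convert suitability to movement
resistance, and delineate core habitats and dispersal corridors together
with their protected-area coverage.

The package is aimed at landscape ecologists and conservation analysts
who want this pipeline as reusable, tested R functions rather than a
chain of GIS operations, plus a seeded synthetic-landscape generator with
a *known* generative suitability model so every stage can be validated by
parameter and scale recovery.

## The models in brief

**Equal-sampling multiscale random forest.** Presences are spatially
thinned to a minimum spacing of 1.2 km; ten pseudo-absence sets of equal
size are drawn under geographic constraints (outside a 3-km presence
buffer, below 4,000 m elevation and 50° slope, spaced ≥ 1.2 km). Every
covariate is computed at six focal scales (radii 1–6 km; moving-window
landscape metrics for land cover, focal means for continuous layers,
densities for villages and roads). For each variable, univariate
500-tree forests on each of the ten balanced datasets pick the scale
with the lowest out-of-bag (OOB) error; the modal scale across datasets
wins. After a |r| > 0.85 collinearity screen, each dataset gets its own
forest, pruned by the Model Improvement Ratio (MIR = permutation
importance / max importance, thresholds 0, 0.1, …, 0.9; the subset with
the lowest OOB error is kept). Habitat suitability HS at a cell is the
mean over the ten forests of the fraction of trees voting presence.

**Resistance.** Movement resistance decays exponentially with
suitability:

    raw = 1000^(−HS),  R = 1 + 99 · (raw − 10⁻³) / (1 − 10⁻³)

so R = 1 where HS = 1 and R = 100 where HS = 0, and most of the
suitability range maps to low resistance.

**Connectivity.** On the 8-neighbor cost graph (edge weight = mean cell
resistance × center distance, so 1 cost unit = 1 m at R = 1), resistant
kernels k = max(0, 1 − cost/θ) are summed over source points at
dispersal thresholds θ = 6,000 / 12,000 / 20,000 cost units; core
habitats are contiguous areas where the summed kernel exceeds 5% of its
maximum. Factorial least-cost paths connect every pair of sources
reachable within 50,000 cost units; Gaussian-buffered paths are summed
into a corridor-density surface. Protected-area coverage of cores and
corridors is reported as extent / protected extent / percent.

## Worked example

```r
library(kernelscape)
cfg <- pipeline_config(
  seed = 42,
  landscape = landscape_config(seed = 42, nrow = 100, ncol = 100),
  variables = c("ELE", "BAM", "Densvil", "TRI", "Disvil"),
  scales = c(1000, 2000, 4000),
  num_trees = 300, auc_reps = 5,
  constraints = absence_constraints(n_sets = 5),
  lcp_sources = 30)
man <- run_pipeline(cfg, out_dir = "run42")
```

which prints (exact numbers from this configuration and seed):

```
stage simulate: 100x100 cells, seed 42
stage prep: thinning 40 occurrences at 1200 m
  retained 20 presences; 5 pseudo-absence sets of 20
stage covariates: 5 variables x 3 scales
stage model: univariate scale optimization
  screened out 0 collinear layer(s)
  mean AUC 0.994 (sd 0.012)
stage resistance
stage connect: kernels at {6000, 12000, 20000} cost units
stage report: core extraction at 0.05 of kernel max
pipeline complete in 4.2 s
```

The manifest then holds the chosen scales and the protection accounting:

```r
data.frame(variable = names(man$chosen_scales),
           scale_m = unlist(man$chosen_scales))
#   variable scale_m
# 1      ELE    1000
# 2      BAM    1000
# 3  Densvil    4000
# 4      TRI    2000
man$report[, 1:4]
#    scenario extent_km2 protected_km2 percent_protected
# 1      6000   129.8750       46.8125          36.04427
# 2     12000   157.8125       59.9375          37.98020
# 3     20000   180.2500       69.2500          38.41886
# 4 corridors   211.1250       68.9375          32.65246
```

Reading the output: the univariate scale optimization recovered the
generative design of the synthetic landscape — the biotic drivers
(elevation `ELE`, bamboo `BAM`) act at the 1-km home-range scale and
village density (`Densvil`) at the 4-km landscape scale. The ensemble
separates presences from pseudo-absences almost perfectly on this
strong-signal landscape (AUC 0.994). Core habitat extent grows from 130
to 180 km² as the assumed dispersal ability rises from 6,000 to 20,000
cost units, while the protected share stays near 36–38% — the kind of
gap analysis the pipeline is built to produce.

All artifacts (rasters, CSV tables, GeoJSON features, JSON manifest with
checksums) land in `run42/`; rerunning the identical configuration
reproduces identical checksums.

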