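---
title: "Dasymetric population mapping and coastal exposure with coastpop"
author: "coastpop maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dasymetric population mapping and coastal exposure with coastpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastpop)
```

## The problem

Census population counts are published for administrative units — in the
setting this package models, Chinese counties (used for fitting) and the
finer Jiedao/Xiangzhen townships (held out for validation). Hazard
assessment in low-elevation coastal zones (LECZ: land below 10 m elevation
and within 100 km of the coast) needs population on a fine grid, because
coarse grids overstate the LECZ land area and the exposed population.
`coastpop` implements the standard answer, dasymetric mapping: predict a
relative density surface from ancillary covariates, then redistribute each
county's census count over its cells in proportion to that surface.

The model core is a county-level regression of log population density.
With six covariate rasters aggregated to county means $\bar x_c$ and
county census density $d_c$ (persons/km²), both engines fit

$$\ln d_c = f(\bar x_c) + \varepsilon_c,$$

and the fitted $f$ is then evaluated *per cell* on the covariate stack.
The prediction surface becomes a weight layer $W$, and counts are
redistributed by the mass-preserving rule

$$\mathrm{POP}_{grid} \;=\; \mathrm{POP}_{county} \times
\frac{W_{grid}}{W_{county}}, \qquad
W_{county} = \sum_{grid \in county} W_{grid},$$

which conserves every county total identically, whatever the weights.

## Covariates

Six predictors, in a fixed layer order:

* **ntl** — nighttime light. The generator convolves settlement intensity
  with a Gaussian blooming kernel (default radius 1000 m), mimicking the
  over-glow that limits the discriminative power of light data in urban
  cores.
* **ndvi_max** — the annual maximum-value composite of 36 ten-day NDVI
  images, $\mathrm{NDVI}_{max} = \max(\mathrm{NDVI}_1, \dots,
  \mathrm{NDVI}_{36})$, the standard cloud-suppressing composite.
  Vegetation is suppressed where built-up fraction is high, so the
  composite correlates negatively with density.
* **elevation** and **slope** — terrain; slope is derived with the Horn
  3×3 finite-difference gradient (the common GIS default), in degrees.
* **guf** — a binary settlement-footprint raster (thresholded settlement
  intensity in the generator).
* **poi_den** — the point-of-interest composite: each of 20 POI
  categories is turned into a density surface with a quartic (biweight)
  planar kernel, bandwidth 2000 m by default,
  $f(x) = \sum_i \frac{3}{\pi h^2}(1 - d_i^2/h^2)^2$ for $d_i < h$, and
  the 20 surfaces are combined into their first principal component.

Two PCA choices were genuinely open and are resolved as follows. The 20
density layers differ in scale by orders of magnitude (category counts in
real POI taxonomies span hundreds to hundreds of thousands), so the PCA is
computed on *standardized* layers (the correlation matrix), with constant
layers dropped. The component's sign is arbitrary, so it is oriented to
correlate non-negatively with the mean of the standardized layers; the
explained-variance fraction is data-dependent and is therefore *reported*
in the stack metadata, never asserted. KDE edge effects are left
uncorrected, consistent with the common GIS implementation; densities near
the domain edge integrate to less than the point count.

## The two regression engines

**Bagged forest** (`fitRandomForest`). A regression random forest (500
trees, `mtry = ceiling(p/3)`) with the in-bag matrix retained. Out-of-bag
(OOB) prediction error is the internal cross-validation; permutation
importance (%IncMSE) is the mean percent increase of OOB MSE over
`nRepeats` independent permutations of one feature column. Because forest
predictions average training targets, the prediction raster can never
leave the training target range — the under-concentration this causes in
extreme urban cores is a recognised property of the approach.

**Rule-based model tree** (`fitModelTree`). An M5-style tree: greedy
binary splits maximize the standard-deviation reduction
$\mathrm{SDR} = sd(S) - \sum_i \tfrac{|S_i|}{|S|} sd(S_i)$; splitting
stops below `2 * minLeaf` rows (default `minLeaf = 4`), when a node's sd
falls below 5 % of the root sd, or when no split has positive gain. Ties
are broken by lowest feature index, then lowest threshold, so refits are
bit-reproducible. Each node carries a least-squares model restricted to
features used in its subtree, simplified by greedy backward elimination
under the penalized error $e \cdot (n+\nu)/(n-\nu)$ ($\nu$ = number of
parameters; $e$ is the mean absolute error, the classic M5 choice);
pruning replaces a subtree by its node model when that does not raise the
penalized error. Predictions are smoothed leaf-to-root with the classic
$k = 15$. The tree exports as rules (conjunctions of split conditions plus
leaf coefficients), and usage-based importance VarImp(%) is the mean of
the share of training rows whose rule conditions test a feature and the
share whose leaf model uses it. Committees and instance-based correction
of the commercial Cubist system are intentionally out of scope; the leaf
linear models are what lets this engine extrapolate beyond the training
target range.

## Weight modes

`weightsFromPrediction` supports two modes, both shipped deliberately:

* `exp` (default): $W = e^{\hat y}$, the back-transform of the ln-density
  model — the statistically natural dasymetric weight.
* `raw`: $W = \max(\hat y, 0)$, the ln prediction used directly. Published
  weight-layer ranges in this literature coincide with ln-prediction
  ranges, implying this was the operational choice. Raw weights are far
  flatter than densities, so they under-concentrate population within
  counties; on synthetic scenes this mode reproduces the classic
  dasymetric bias signature (see below) while the `exp` mode largely
  removes it. County totals are identical in both modes — only the
  within-county allocation differs.

## Validation

Township censuses are never used in fitting; `evaluatePopulation` compares
the zonal sums of the population grid with them: MAE, RMSE, %RMSE
(RMSE as a share of mean census count), MRE% (mean absolute relative
error over positive-census units — the formula is not fixed by convention,
so the package documents this choice and counts excluded zero-census
units), and $R^2$ as the squared Pearson correlation of log10 densities
over units with positive census and prediction. `stratifiedReport` cuts
units at the 20th/80th percentiles of census density (ties to the lower
stratum) and reports the mean signed log10 error per stratum: dasymetric
smoothing shows up as a negative mean in the top stratum (dense townships
under-filled) and a positive mean in the bottom stratum (sparse townships
over-filled). `ablationCompare` reruns the identical pipeline with the POI
composite replaced by an all-zero layer, isolating the contribution of POI
data exactly.

## What the synthetic generator emulates — and what it does not

`generateScene` builds seeded scenes with the statistical structure the
method assumes: a planar-metric coastal domain (sea strip to the west), an
elevation ramp rising from the coast with smooth noise, Gaussian
settlement blobs biased to low elevation, observable covariates derived
from those fields (bloomed light, built-up-suppressed NDVI, thresholded
footprint), a true density surface that is log-linear in the covariates
plus a settlement term and spatially correlated noise, POIs drawn from an
inhomogeneous Poisson field with intensity proportional to true
population, and a three-level nested Voronoi admin partition whose census
counts are *exact* zonal sums of the true surface.

Defaults were fixed once, as study conditions, and the reasoning is:

* **512 × 512 cells of 100 m** — the target mapping resolution on a
  domain that runs end-to-end in seconds on one CPU; tests use smaller
  grids where the property under test allows it (stated per test).
* **80 counties × 5 townships, 4 provinces** — enough fitting rows for a
  forest and a 5:1 validation-to-fitting unit ratio, mirroring the
  county/township design of the real census hierarchy at reduced scale.
* **Coefficients** (`beta`, `settlementBoost`) are scaled so county-level
  ln densities span roughly 3–10 — about seven ln units, the spread
  reported for the real county data (1.33–8.25).
* **Noise** `sd = 0.3` ln units with a 1 km correlation length. The
  correlation matters: white cell-level noise would average out inside
  validation townships and make held-out assessment trivially optimistic,
  whereas real unexplained density variation is spatially structured. The
  noise field is drawn for every scene (then scaled), so scenes with the
  same seed share all other components across noise levels — enabling
  paired comparisons.
* **Settlement radii 5–12 % of the domain extent** — city-scale blobs
  comparable to county size, so dense counties are dense throughout, as
  real urban districts are. With much smaller blobs a "dense county" is
  one packed township plus near-empty siblings, an admin/settlement
  geometry mismatch that changes the within-county error structure.
* **POI rates** span three orders of magnitude across the 20 category
  slots (~2 points per 1000 persons in total), mirroring the very uneven
  real category counts.

The generator does **not** emulate: realistic coastline geometry or admin
boundary shapes, semantic differences between POI categories (they differ
only in rate), NTL saturation (only blooming), spatial covariance between
covariate errors, or migration/daytime population. Passing tests therefore
demonstrate that the pipeline machinery is correct and that the method
behaves as published *under its own assumptions* — not that it attains any
particular accuracy on real census data.

## Numerical choices and degenerate inputs

* Redistribution is exact in expectation and in floating point: per-county
  sums match census to ~1e-15 relative; a county whose weights are all
  zero falls back to uniform allocation (warned); a county with census but
  no valid cells is an error.
* LECZ thresholds are strict (`< 10 m`, `< 100 km`): a cell at exactly
  10 m is excluded, following the zone's definitional wording; the
  coast-connectivity filter (8-connected components reachable from the
  coast) is off by default because the plain three-step overlay does not
  enforce contiguity, but is offered as an option.
* Distance to coast is an exact Euclidean distance transform on cell
  centres; the vector coastline buffer of operational GIS work is thereby
  approximated to within one cell.
* Zonal statistics flag units with no valid cells as missing (`NA`), never
  as zero; training-table assembly drops such units (and zero-census
  units, whose ln density is undefined) with a logged count.
* All randomness is seeded; both engines are deterministic given seed and
  input order; pipeline artifacts are written with fixed formatting so
  identical configurations produce byte-identical files, verified by MD5
  in the run manifest.
* Rasters are carried as plain-text ASCII grids with a `.prj` sidecar for
  the CRS tag; the tag is compared for equality only — reprojection is out
  of scope and the working space is assumed planar-metric (an equal-area
  projection).

## Known limitations

The M5 engine is a single model tree, not a Cubist committee; its accuracy
is therefore a lower bound on what the commercial system reports. MRE is
sensitive to very small census counts, which the synthetic scenes produce
in sparsely settled townships. DEM error propagation into the LECZ mask is
acknowledged but not modelled. The PCA composite keeps one component only;
on scenes where categories carry genuinely different spatial signals a
single component would lose information.

## A worked run

```{r example, eval = FALSE}
cfg <- defaultRunConfig(seed = 1, outputDir = "run1")
manifest <- runPipeline(cfg)
manifest$metrics$township$rf
```

The run writes covariate rasters, both population grids, the LECZ mask,
exposure tables and a manifest with per-file hashes under `run1/`;
`scripts/acceptance.R` repeats the same computation from scratch and
stores the headline numbers as JSON.
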