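# coastpop

Dasymetric population mapping with point-of-interest (POI) covariates, and
population-exposure accounting for low-elevation coastal zones (LECZ).

Census population counts exist per administrative unit; coastal-hazard
assessment needs them on a fine grid, because a coarse grid overstates
both the land area and the population of the zone below 10 m elevation and
within 100 km of the coast. `coastpop` is for spatial demographers and
coastal-risk analysts who want that disaggregation pipeline as tested,
reusable R functions — including a seeded synthetic-landscape generator,
so the whole method can be exercised and validated end to end without any
restricted census, POI or elevation download.

## The method

Six covariate rasters are built on a common 100 m grid: nighttime light,
the annual maximum NDVI composite `NDVI_max = max(NDVI_1, …, NDVI_36)`,
elevation, Horn-method slope, a binary settlement footprint, and a POI
density composite (quartic-kernel densities of 20 POI categories,
bandwidth 2000 m, reduced to their first principal component). County
census densities give the regression target

    ln d_county = f(county means of the six covariates) + ε,

fitted two ways: a bagged random-forest ensemble (with out-of-bag error
and permutation importance, %IncMSE) and an M5-style rule-based model
tree (SDR splits, leaf linear models, penalized-error pruning, VarImp(%)
usage importance). The fitted model, evaluated per cell, becomes a weight
layer `W`, and census counts are redistributed mass-preservingly:

    POP_grid = POP_county × W_grid / W_county .

Per-county grid sums equal the census identically. Accuracy is assessed
against finer township censuses that never enter the fit, overall and
within density strata (bottom 20 % / middle 60 % / top 20 %), where the
characteristic dasymetric smoothing bias — under-filling dense townships,
over-filling sparse ones — is measured. Finally the population grid is
overlaid with the LECZ mask (elevation < 10 m and coast distance
< 100 km, strict) to account exposed population per region.

## A worked example

```r
library(coastpop)

scene <- generateScene(sceneConfig(seed = 1))   # default 512 x 512 scene
scene
#> Scene: 512 x 512 grid (100 m cells), seed 1
#>   population: 2000000 persons on 183296 land cells; 3590 POIs in 20 categories
#> AdminLayer: 4 provinces, 80 counties, 400 townships on 512 x 512 grid
#>   census total (township level): 2000000 persons

stack <- buildCovariateStack(scene)             # six aligned covariates
tab   <- buildTrainingTable(stack, scene@admin, "county")
rf    <- fitRandomForest(tab, nTrees = 500, seed = 2)
rf
#> FittedModel (rf): 6 features, training y range [3.189, 9.173]
#>   OOB MSE: 0.0513

pop <- redistribute(weightsFromPrediction(predictRaster(rf, stack), "exp"),
                    scene@admin)
evaluatePopulation(pop, scene@admin, "township")
#>  mean  mre_pct      mae     rmse pct_rmse    r2_log n_units n_excluded
#>  5000 16.27333 669.6556 2244.457 44.88914 0.9821142     400          0

mask <- extractLecz(scene@elevation, distanceToCoast(scene@landMask),
                    scene@landMask)
exposureTable(pop, mask, scene@admin, "province")
#>  region_id exposed_pop total_pop pct_exposed
#>          0     1325572   2000000      66.279
#>          1        5144    213070       2.414
#>          2      873262   1253599      69.660
#>          3       38564     71876      53.653
#>          4      408602    461456      88.546
```

Reading the output: the forest explains the county log densities almost
exactly (OOB MSE 0.05 on a target spanning ~6 ln units); redistributed to
the grid and re-aggregated to the 400 held-out townships it reaches a
log-density R² of 0.982 with a mean absolute error of ~670 persons per
township (mean township population 5000), and the per-county sums equal
the census by construction. Region 0 in the exposure table is the global
row: two thirds of this synthetic coastal population lives inside the
LECZ, with province-level exposure ranging from 2 % (the inland province)
to 89 %.

`runPipeline(defaultRunConfig(seed = 1))` packages all of the above —
both engines, mapping, LECZ overlay, validation — and writes every
artifact plus a hash manifest; identical configuration and seed give
byte-identical outputs. A thin command-line wrapper with `run`, `synth`,
`validate` and `ablate` subcommands is installed at
`inst/scripts/coastpop`.

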