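Package: coastpop
Title: Dasymetric Population Mapping and Coastal Exposure with POI Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for POI-enhanced dasymetric population mapping and
    low-elevation coastal-zone (LECZ) exposure accounting. Builds covariate
    rasters (annual-maximum NDVI composite, quartic-kernel POI densities and
    their first principal component, nighttime light, terrain, settlement
    footprint), fits county-level log-density regressions with a bagged
    random-forest ensemble and an M5-style rule-based model tree,
    redistributes census counts to a fine grid with exact mass conservation,
    and validates predictions against held-out township censuses. A seeded
    synthetic-landscape generator emulates the statistical structure of the
    real inputs so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    EBImage,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coastpop-package.R'
    'utils.R'
    'geodata-raster.R'
    'covariates.R'
    'geodata-zonal.R'
    'dasymetric.R'
    'm5.R'
    'rf.R'
    'evaluation.R'
    'lecz.R'
    'synthgen.R'
    'pipeline.R'
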