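#' @import methods
NULL

#' Grid geometry of a raster
#'
#' A \code{GridSpec} describes the geometry every raster in a run shares:
#' grid dimensions, the map coordinate of the upper-left (north-west) corner,
#' the square cell size in metres, and an opaque CRS tag. Row 1 is the
#' northernmost row; the centre of cell \code{(r, c)} sits at
#' \code{(originX + (c - 0.5) * cellSize, originY - (r - 0.5) * cellSize)}.
#' The CRS tag is carried and compared for equality only; the package works
#' in an already-projected planar metric space (an equal-area working grid).
#'
#' @slot nRows,nCols integer grid dimensions (>= 1).
#' @slot originX,originY map coordinates (m) of the north-west corner.
#' @slot cellSize square cell edge length in metres (> 0); default 100 m.
#' @slot crsTag opaque coordinate-system label, checked for equality only.
#' @aliases GridSpec
#' @exportClass GridSpec
setClass("GridSpec",
  representation(
    nRows = "integer", nCols = "integer",
    originX = "numeric", originY = "numeric",
    cellSize = "numeric", crsTag = "character"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single integer >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single integer >= 1")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@crsTag) != 1L || is.na(object@crsTag))
    msg <- c(msg, "crsTag must be a single string")
  if (length(msg)) msg else TRUE
})

#' Single-band raster on a GridSpec
#'
#' A \code{GeoRaster} couples a numeric matrix of cell values with its
#' [GridSpec-class]. Missing cells (nodata) are represented as \code{NA};
#' they take part in masking only, never in arithmetic. The \code{nodata}
#' slot records the sentinel used when the raster is written to disk.
#'
#' @slot spec the [GridSpec-class] of the grid.
#' @slot values numeric matrix, \code{nRows x nCols}; \code{NA} = nodata.
#' @slot nodata numeric sentinel used for file output (default -9999).
#' @aliases GeoRaster
#' @exportClass GeoRaster
setClass("GeoRaster",
  representation(spec = "GridSpec", values = "matrix", nodata = "numeric")
)

setValidity("GeoRaster", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (!identical(dim(object@values),
                 c(as.integer(object@spec@nRows), as.integer(object@spec@nCols))))
    msg <- c(msg, "values dimensions must match the GridSpec")
  if (length(object@nodata) != 1L)
    msg <- c(msg, "nodata must be a single number")
  if (length(msg)) msg else TRUE
})

#' Nested administrative partition with census counts
#'
#' An \code{AdminLayer} stores the administrative geography as a label
#' raster at the finest (township) level plus a unit table covering three
#' nested levels: province > county > township. Labels of coarser levels
#' are derived through the parent chain, so nesting holds by construction.
#' A label of 0 marks cells outside every unit (sea).
#'
#' @slot labels integer-valued [GeoRaster-class] of township unit ids
#'   (0 = outside).
#' @slot units \code{data.frame} with columns \code{unit_id} (integer,
#'   unique across levels), \code{level} (one of \code{"province"},
#'   \code{"county"}, \code{"township"}), \code{parent_id} (0 for
#'   provinces), \code{census_pop} (persons; may be \code{NA} before
#'   [aggregateCensus()]), \code{area_km2}.
#' @aliases AdminLayer
#' @exportClass AdminLayer
setClass("AdminLayer",
  representation(labels = "GeoRaster", units = "data.frame")
)

setValidity("AdminLayer", function(object) {
  u <- object@units
  need <- c("unit_id", "level", "parent_id", "census_pop", "area_km2")
  if (!all(need %in% names(u)))
    return(paste("units table must have columns:", paste(need, collapse = ", ")))
  if (!all(u$level %in% c("province", "county", "township")))
    return("unit level must be province, county or township")
  if (anyDuplicated(u$unit_id))
    return("unit_id must be unique across levels")
  lab <- object@labels@values
  present <- unique(lab[!is.na(lab) & lab != 0])
  twp <- u$unit_id[u$level == "township"]
  if (!all(present %in% twp))
    return("every nonzero label must be a township unit_id")
  # parent consistency: township -> county -> province
  cty <- u$unit_id[u$level == "county"]
  prv <- u$unit_id[u$level == "province"]
  if (!all(u$parent_id[u$level == "township"] %in% cty))
    return("every township must nest within exactly one county")
  if (!all(u$parent_id[u$level == "county"] %in% prv))
    return("every county must nest within exactly one province")
  TRUE
})

#' Aligned stack of the six model covariates
#'
#' Holds the six predictor rasters used for the county-level log-density
#' regression, in a fixed, documented order: \code{ntl} (nighttime light),
#' \code{ndvi_max} (annual maximum NDVI composite), \code{elevation} (m),
#' \code{slope} (degrees), \code{guf} (binary settlement footprint) and
#' \code{poi_den} (first principal component of the per-category POI kernel
#' densities). The fixed order keeps model feature names stable across runs.
#'
#' @slot layers named list of six aligned [GeoRaster-class] objects.
#' @slot spec the shared [GridSpec-class].
#' @slot metadata provenance list (KDE bandwidth, PCA explained-variance
#'   fraction, layer order).
#' @aliases CovariateStack
#' @exportClass CovariateStack
setClass("CovariateStack",
  representation(layers = "list", spec = "GridSpec", metadata = "list")
)

setValidity("CovariateStack", function(object) {
  if (!identical(names(object@layers), covariateNames()))
    return(paste("layers must be named, in order:",
                 paste(covariateNames(), collapse = ", ")))
  for (nm in names(object@layers)) {
    r <- object@layers[[nm]]
    if (!is(r, "GeoRaster")) return("each layer must be a GeoRaster")
    if (!sameGrid(r@spec, object@spec))
      return(sprintf("layer '%s' is not aligned with the stack grid", nm))
  }
  TRUE
})

#' Configuration of a synthetic coastal scene
#'
#' Parameters of the seeded synthetic-landscape generator
#' ([generateScene()]). The generator emulates the statistical structure the
#' mapping method assumes: a planar-metric coastal domain, settlement-
#' concentrated population whose log density is a noisy log-linear function
#' of the covariates, POI points whose intensity tracks population, and
#' nested admin partitions whose census counts are exact zonal sums of the
#' true surface. See the methods vignette for the rationale behind each
#' default.
#'
#' @slot spec target [GridSpec-class] (default 512 x 512 cells of 100 m).
#' @slot seed integer RNG seed; the scene is deterministic in it.
#' @slot nProvinces,nCounties,townshipsPerCounty admin partition sizes.
#' @slot nSettlements number of Gaussian settlement intensity blobs.
#' @slot beta length-6 coefficient vector on the standardized covariates
#'   (ntl, ndvi, elevation, slope, guf, poi-proxy) in the true ln-density
#'   model.
#' @slot settlementBoost extra ln-density term per unit of normalized
#'   settlement intensity (the within-county heterogeneity dasymetric
#'   mapping exists to capture).
#' @slot noiseSd standard deviation of the ln-density noise (ln units).
#' @slot noiseCorrLength spatial correlation length of the ln-density
#'   noise (m); correlated noise survives aggregation to validation
#'   units, as unexplained density variation does in real data.
#' @slot totalPop total population of the scene (persons).
#' @slot poiRatePerCapita length-20 per-category POI rates (points per
#'   person).
#' @slot ntlBloomingRadius Gaussian blooming radius of the nighttime-light
#'   sensor (m).
#' @slot coastFraction fraction of the domain covered by sea (west side).
#' @slot elevGradient mean elevation rise per metre of distance from the
#'   coast (m/m).
#' @slot elevNoiseSd standard deviation of the smooth elevation noise (m).
#' @slot settlementSigmaRange settlement blob radius range, as a fraction
#'   of the larger grid dimension.
#' @aliases SceneConfig
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(
    spec = "GridSpec", seed = "integer",
    nProvinces = "integer", nCounties = "integer",
    townshipsPerCounty = "integer", nSettlements = "integer",
    beta = "numeric", settlementBoost = "numeric", noiseSd = "numeric",
    noiseCorrLength = "numeric",
    totalPop = "numeric", poiRatePerCapita = "numeric",
    ntlBloomingRadius = "numeric", coastFraction = "numeric",
    elevGradient = "numeric", elevNoiseSd = "numeric",
    settlementSigmaRange = "numeric"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  cnt <- c(object@nProvinces, object@nCounties, object@townshipsPerCounty,
           object@nSettlements)
  if (any(is.na(cnt)) || any(cnt < 1L))
    msg <- c(msg, "all counts must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@beta) != 6L)
    msg <- c(msg, "beta must have 6 entries (ntl, ndvi, elev, slope, guf, poi-proxy)")
  if (length(object@poiRatePerCapita) != 20L || any(object@poiRatePerCapita < 0))
    msg <- c(msg, "poiRatePerCapita must be 20 non-negative rates")
  if (object@coastFraction <= 0 || object@coastFraction >= 1)
    msg <- c(msg, "coastFraction must be in (0, 1)")
  if (object@totalPop <= 0) msg <- c(msg, "totalPop must be positive")
  if (object@ntlBloomingRadius <= 0) msg <- c(msg, "ntlBloomingRadius must be > 0")
  if (length(msg)) msg else TRUE
})

#' A generated synthetic coastal scene
#'
#' The output of [generateScene()]: the covariate rasters, the true
#' population surface, the nested admin partition with exact census counts,
#' the POI point table and the land mask — everything the downstream
#' pipeline consumes. All rasters share one [GridSpec-class]; census counts
#' at every admin level are exact zonal sums of \code{truePop}.
#'
#' @slot ntl,elevation,slope,guf,truePop,landMask [GeoRaster-class] layers.
#'   \code{truePop} is persons per cell, \code{NA} at sea; \code{landMask}
#'   is 1 on land, 0 at sea.
#' @slot ndviSeries list of 36 ten-day NDVI composites ([GeoRaster-class]).
#' @slot admin [AdminLayer-class] with census at all three levels.
#' @slot pois \code{data.frame(x, y, category)} of POI points over 20
#'   category slots.
#' @slot config the [SceneConfig-class] that produced the scene.
#' @aliases Scene
#' @exportClass Scene
setClass("Scene",
  representation(
    ntl = "GeoRaster", ndviSeries = "list", elevation = "GeoRaster",
    slope = "GeoRaster", guf = "GeoRaster", truePop = "GeoRaster",
    admin = "AdminLayer", pois = "data.frame", landMask = "GeoRaster",
    config = "SceneConfig"
  )
)

#' A fitted county-level log-density regression
#'
#' Wraps either the bagged random-forest ensemble (\code{kind = "rf"}) or
#' the M5-style rule-based model tree (\code{kind = "m5"}). Both predict
#' ln(persons per km^2) from the six covariates. The training target range
#' is retained because the two engines behave differently outside it: the
#' forest, averaging training targets, can never leave the range, while the
#' model tree's leaf linear models extrapolate.
#'
#' @slot kind \code{"rf"} or \code{"m5"}.
#' @slot fit the underlying fit object (a \code{randomForest} or the model
#'   tree structure).
#' @slot features character vector of the feature names, in training order.
#' @slot yRange numeric length 2: range of the training target.
#' @slot oobMSE out-of-bag mean squared error (\code{NA} for the model
#'   tree, which has no bagging).
#' @slot importance per-feature importance table: \code{\%IncMSE} for the
#'   forest, \code{VarImp(\%)} for the model tree.
#' @slot rules for the model tree, the extracted rule list (conditions plus
#'   leaf linear coefficients); empty for the forest.
#' @aliases FittedModel
#' @exportClass FittedModel
setClass("FittedModel",
  representation(
    kind = "character", fit = "ANY", features = "character",
    yRange = "numeric", oobMSE = "numeric",
    importance = "data.frame", rules = "list"
  )
)

setValidity("FittedModel", function(object) {
  if (!object@kind %in% c("rf", "m5"))
    return("kind must be 'rf' or 'm5'")
  if (length(object@yRange) != 2L)
    return("yRange must have length 2")
  TRUE
})
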