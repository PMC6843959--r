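#' @include AllClasses.R
NULL

#' Extract the value matrix of a raster
#'
#' @param x a [GeoRaster-class].
#' @return numeric matrix (\code{NA} = nodata).
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' Extract the grid geometry of an object
#'
#' @param x a [GeoRaster-class], [CovariateStack-class] or [Scene-class].
#' @return the object's [GridSpec-class].
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' Nodata mask of a raster
#'
#' @param x a [GeoRaster-class].
#' @return logical matrix, \code{TRUE} where the cell is nodata.
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' Unit table of an administrative layer
#'
#' @param x an [AdminLayer-class].
#' @param level optional level filter (\code{"province"}, \code{"county"},
#'   \code{"township"}).
#' @return \code{data.frame} of units.
#' @export
setGeneric("adminUnits", function(x, level = NULL) standardGeneric("adminUnits"))

#' Label raster of an administrative layer at a chosen level
#'
#' Township labels are stored; county and province labels are derived by
#' following the parent chain, so the three levels nest exactly.
#'
#' @param x an [AdminLayer-class].
#' @param level \code{"township"} (stored), \code{"county"} or
#'   \code{"province"} (derived).
#' @return integer-valued [GeoRaster-class] (0 = outside).
#' @export
setGeneric("labelRaster", function(x, level = "township")
  standardGeneric("labelRaster"))

#' Layers of a covariate stack
#'
#' @param x a [CovariateStack-class].
#' @return named list of the six [GeoRaster-class] layers, in the fixed
#'   order \code{ntl, ndvi_max, elevation, slope, guf, poi_den}.
#' @export
setGeneric("stackLayers", function(x) standardGeneric("stackLayers"))
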