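#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Zonal statistic of a raster over a label raster
#'
#' Aggregates the value raster per label (admin unit), over non-nodata
#' cells only. Labels with zero valid cells are reported with \code{NA}
#' (flagged missing), never silently as 0 — a unit whose covariate is
#' entirely nodata must be distinguishable from a unit whose sum is zero.
#'
#' @param value [GeoRaster-class] of values.
#' @param labels integer-valued [GeoRaster-class] of unit labels (0 or
#'   \code{NA} = outside all units), aligned with \code{value}.
#' @param stat \code{"mean"}, \code{"sum"} or \code{"count"}.
#' @return \code{data.frame(unit_id, value)}, one row per label present in
#'   the label raster, sorted by \code{unit_id}.
#' @export
zonalAggregate <- function(value, labels, stat = c("mean", "sum", "count")) {
  stat <- match.arg(stat)
  stopifnot(is(value, "GeoRaster"), is(labels, "GeoRaster"))
  stopIfMisaligned(value@spec, labels@spec, "value and label rasters")
  l <- as.vector(labels@values)
  v <- as.vector(value@values)
  zone <- !is.na(l) & l != 0
  ids <- sort(unique(l[zone]))
  ok <- zone & !is.na(v)
  g <- l[ok]
  sums <- rowsum(v[ok], g)                      # rownames = labels with valid cells
  cnts <- rowsum(rep(1, length(g)), g)
  res <- switch(stat,
    sum   = sums[, 1],
    count = cnts[, 1],
    mean  = sums[, 1] / cnts[, 1])
  out <- res[match(as.character(ids), rownames(sums))] # absent -> NA (flagged)
  data.frame(unit_id = ids, value = as.numeric(out), row.names = NULL)
}

#' Euclidean distance to the coast
#'
#' For each land cell, the centre-to-centre Euclidean distance in metres to
#' the nearest sea cell; sea cells get 0. The coastline the distances refer
#' to is the rasterized land/sea boundary, which approximates a vector
#' coastline buffer to within one cell.
#'
#' @param landMask [GeoRaster-class], 1 (or \code{TRUE}) on land, 0 at sea;
#'   no nodata cells allowed.
#' @return [GeoRaster-class] of distances in metres.
#' @export
distanceToCoast <- function(landMask) {
  stopifnot(is(landMask, "GeoRaster"))
  m <- landMask@values
  if (anyNA(m)) stop("land mask must not contain nodata cells", call. = FALSE)
  m <- (m != 0) * 1
  if (all(m == 1))
    stop("land mask contains no sea cells; there is no coastline", call. = FALSE)
  d <- EBImage::distmap(m, metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(m), ncol(m)) * landMask@spec@cellSize
  geoRaster(d, landMask@spec, nodata = landMask@nodata)
}

# ---- administrative layers ----------------------------------------------

#' Create an administrative layer
#'
#' @param labels integer-valued [GeoRaster-class] of township labels
#'   (0 = outside).
#' @param units unit table; see [AdminLayer-class]. \code{area_km2} is
#'   recomputed from the label raster when missing.
#' @return an [AdminLayer-class].
#' @export
adminLayer <- function(labels, units) {
  units <- as.data.frame(units)
  if (is.null(units$census_pop)) units$census_pop <- NA_real_
  if (is.null(units$area_km2)) units$area_km2 <- NA_real_
  obj <- new("AdminLayer", labels = labels, units = units)
  obj@units$area_km2 <- unitAreas(obj)
  obj
}

# cell-count-derived areas (km^2) for every unit at every level
unitAreas <- function(admin) {
  u <- admin@units
  cellKm2 <- (admin@labels@spec@cellSize / 1000)^2
  areas <- numeric(nrow(u))
  for (lev in c("township", "county", "province")) {
    sel <- u$level == lev
    if (!any(sel)) next
    lab <- labelRaster(admin, lev)@values
    cnt <- table(factor(lab[lab != 0 & !is.na(lab)], levels = u$unit_id[sel]))
    areas[sel] <- as.numeric(cnt) * cellKm2
  }
  areas
}

#' @describeIn adminUnits unit table, optionally filtered by level
#' @export
setMethod("adminUnits", "AdminLayer", function(x, level = NULL) {
  u <- x@units
  if (!is.null(level)) {
    level <- match.arg(level, c("province", "county", "township"))
    u <- u[u$level == level, , drop = FALSE]
  }
  row.names(u) <- NULL
  u
})

#' @describeIn labelRaster derive labels at any of the three levels
#' @export
setMethod("labelRaster", "AdminLayer", function(x, level = "township") {
  level <- match.arg(level, c("township", "county", "province"))
  if (level == "township") return(x@labels)
  u <- x@units
  twp <- u[u$level == "township", ]
  toCounty <- twp$parent_id[match(x@labels@values, twp$unit_id)]
  toCounty[is.na(toCounty)] <- 0
  if (level == "county") {
    out <- matrix(toCounty, nrow(x@labels@values), ncol(x@labels@values))
  } else {
    cty <- u[u$level == "county", ]
    toProv <- cty$parent_id[match(toCounty, cty$unit_id)]
    toProv[is.na(toProv)] <- 0
    out <- matrix(toProv, nrow(x@labels@values), ncol(x@labels@values))
  }
  geoRaster(out, x@labels@spec, nodata = x@labels@nodata)
})

setMethod("show", "AdminLayer", function(object) {
  u <- object@units
  cat(sprintf("AdminLayer: %d provinces, %d counties, %d townships on %d x %d grid\n",
              sum(u$level == "province"), sum(u$level == "county"),
              sum(u$level == "township"),
              object@labels@spec@nRows, object@labels@spec@nCols))
  if (all(is.na(u$census_pop))) cat("  census: not yet populated\n")
  else cat(sprintf("  census total (township level): %.0f persons\n",
                   sum(u$census_pop[u$level == "township"], na.rm = TRUE)))
})

# census lookup for one level, aligned to the level's unit table order
censusAt <- function(admin, level) {
  u <- adminUnits(admin, level)
  if (all(is.na(u$census_pop)))
    stop("census counts are not populated at the ", level,
         " level; run aggregateCensus() first", call. = FALSE)
  u
}
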