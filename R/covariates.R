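#' @include AllClasses.R AllGenerics.R utils.R geodata-raster.R
NULL

#' Annual maximum-value composite of an NDVI series
#'
#' Cell-wise maximum over the non-nodata values of an image series (the
#' standard 36 x 10-day annual composite that suppresses cloud
#' contamination and separates settlements from bare soil). A cell that is
#' nodata in every image stays nodata.
#'
#' @param series list of aligned [GeoRaster-class] images (at least one).
#' @return [GeoRaster-class] of per-cell maxima.
#' @export
maxComposite <- function(series) {
  if (!length(series)) stop("empty image series", call. = FALSE)
  stopifnot(all(vapply(series, is, logical(1), "GeoRaster")))
  spec <- series[[1]]@spec
  for (img in series) stopIfMisaligned(spec, img@spec, "series images")
  out <- series[[1]]@values
  for (img in series[-1]) out <- pmax(out, img@values, na.rm = TRUE)
  geoRaster(out, spec, nodata = series[[1]]@nodata)
}

#' Quartic-kernel density surface of one POI category
#'
#' Evaluates the planar kernel density estimate at every cell centre:
#' \deqn{f(x) = \sum_i \frac{3}{\pi h^2}\left(1 - d_i^2/h^2\right)^2,
#'   \quad d_i = |x - p_i| < h,}
#' the quartic (biweight) kernel used by the common GIS planar KDE tools,
#' in units of points per square metre. Cells farther than the bandwidth
#' from every point are exactly zero. No boundary correction is applied
#' (densities near the domain edge integrate to less than the point
#' count), matching standard GIS behaviour.
#'
#' @param pois \code{data.frame(x, y, category)} of points.
#' @param category the category id to estimate.
#' @param spec target [GridSpec-class].
#' @param bandwidth kernel bandwidth h in metres (default 2000).
#' @return [GeoRaster-class] of densities (points/m^2).
#' @export
kdeDensity <- function(pois, category, spec, bandwidth = 2000) {
  stopifnot(is(spec, "GridSpec"))
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (!category %in% c(pois$category, 1:20))
    stop("unknown POI category: ", category, call. = FALSE)
  p <- pois[pois$category == category, , drop = FALSE]
  nr <- spec@nRows; nc <- spec@nCols; cs <- spec@cellSize
  out <- matrix(0, nr, nc)
  if (!nrow(p)) return(geoRaster(out, spec))
  h2 <- bandwidth^2
  norm <- 3 / (pi * h2)
  hc <- bandwidth / cs
  for (i in seq_len(nrow(p))) {
    # fractional (1-based) grid coordinates of the point
    gc <- (p$x[i] - spec@originX) / cs + 0.5
    gr <- (spec@originY - p$y[i]) / cs + 0.5
    r1 <- max(1L, ceiling(gr - hc)); r2 <- min(nr, floor(gr + hc))
    c1 <- max(1L, ceiling(gc - hc)); c2 <- min(nc, floor(gc + hc))
    if (r1 > r2 || c1 > c2) next
    dr <- (r1:r2 - gr) * cs
    dc <- (c1:c2 - gc) * cs
    d2 <- outer(dr^2, dc^2, "+")
    w <- 1 - d2 / h2
    w[w < 0] <- 0
    out[r1:r2, c1:c2] <- out[r1:r2, c1:c2] + norm * w^2
  }
  geoRaster(out, spec)
}

#' First-principal-component composite of POI density layers
#'
#' Standardizes each density layer over its valid cells (the 20 category
#' layers differ in scale by orders of magnitude), drops degenerate
#' (constant) layers with a warning, and returns the per-cell score of the
#' first principal component of the remaining layers, with its sign
#' oriented so the composite correlates non-negatively with the mean of
#' the standardized layers. The explained-variance fraction is returned
#' alongside — it is data-dependent and reported, never asserted.
#'
#' @param densityStack list of aligned [GeoRaster-class] density layers
#'   (at least two non-degenerate).
#' @return list with elements \code{raster} ([GeoRaster-class] PC1 score),
#'   \code{varFraction} (explained-variance fraction of PC1) and
#'   \code{dropped} (indices of degenerate layers).
#' @export
poiComposite <- function(densityStack) {
  if (length(densityStack) < 2L)
    stop("need at least two density layers", call. = FALSE)
  spec <- densityStack[[1]]@spec
  for (r in densityStack) stopIfMisaligned(spec, r@spec, "density layers")
  m <- vapply(densityStack, function(r) as.vector(r@values),
              numeric(spec@nRows * spec@nCols))
  valid <- rowSums(is.na(m)) == 0
  sds <- apply(m[valid, , drop = FALSE], 2, stats::sd)
  degenerate <- which(!is.finite(sds) | sds < .Machine$double.eps^0.5)
  if (length(degenerate)) {
    warning(length(degenerate),
            " degenerate (constant) density layer(s) dropped from the PCA")
    m <- m[, -degenerate, drop = FALSE]
  }
  if (ncol(m) < 2L)
    stop("fewer than two non-degenerate density layers", call. = FALSE)
  pc <- stats::prcomp(m[valid, , drop = FALSE], center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  zmean <- rowMeans(scale(m[valid, , drop = FALSE]))
  if (stats::cor(score, zmean) < 0) score <- -score
  out <- rep(NA_real_, nrow(m))
  out[valid] <- score
  list(raster = geoRaster(matrix(out, spec@nRows, spec@nCols), spec),
       varFraction = pc$sdev[1]^2 / sum(pc$sdev^2),
       dropped = degenerate)
}

#' Assemble the six-covariate stack from a scene
#'
#' Builds the aligned predictor stack in its fixed order (\code{ntl},
#' \code{ndvi_max}, \code{elevation}, \code{slope}, \code{guf},
#' \code{poi_den}): the annual NDVI maximum composite, the pass-through
#' terrain/light/settlement layers, and the first-principal-component
#' composite of the 20 per-category POI kernel densities. All layers are
#' masked to land. With \code{includePoi = FALSE} (the ablation path) or a
#' scene without POIs, \code{poi_den} is an all-zero layer and a warning is
#' logged. KDE bandwidth and the realized PCA variance fraction are
#' recorded in the stack metadata.
#'
#' @param scene a [Scene-class].
#' @param bandwidth POI KDE bandwidth in metres (default 2000).
#' @param includePoi include the POI composite? \code{FALSE} reproduces
#'   the five-covariate ablation.
#' @return a [CovariateStack-class].
#' @export
buildCovariateStack <- function(scene, bandwidth = 2000, includePoi = TRUE) {
  stopifnot(is(scene, "Scene"))
  spec <- gridSpec(scene)
  landNA <- function(r) {
    v <- r@values
    v[scene@landMask@values == 0] <- NA_real_
    geoRaster(v, spec)
  }
  meta <- list(bandwidth = bandwidth, pcaVarFraction = NA_real_,
               layerOrder = covariateNames())
  if (includePoi && nrow(scene@pois)) {
    dens <- lapply(1:20, function(k)
      kdeDensity(scene@pois, k, spec, bandwidth))
    comp <- poiComposite(dens)
    poiDen <- landNA(comp$raster)
    meta$pcaVarFraction <- comp$varFraction
  } else {
    warning("POI composite disabled or no POIs in scene; ",
            "poi_den is an all-zero layer (ablation path)")
    poiDen <- landNA(geoRaster(matrix(0, spec@nRows, spec@nCols), spec))
  }
  layers <- list(
    ntl = landNA(scene@ntl),
    ndvi_max = landNA(maxComposite(scene@ndviSeries)),
    elevation = landNA(scene@elevation),
    slope = landNA(scene@slope),
    guf = landNA(scene@guf),
    poi_den = poiDen
  )
  new("CovariateStack", layers = layers, spec = spec, metadata = meta)
}

#' Write stack provenance metadata to a JSON sidecar
#'
#' @param stack a [CovariateStack-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeStackMetadata <- function(stack, path) {
  jsonlite::write_json(stack@metadata, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
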