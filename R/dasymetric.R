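#' @include AllClasses.R AllGenerics.R utils.R geodata-zonal.R covariates.R
NULL

#' Build the county-level training table
#'
#' One row per admin unit at the chosen level: the zonal means of the six
#' covariates as features and \code{y = ln(census_pop / area_km2)} — the
#' natural logarithm of census population density in persons per km^2 — as
#' the target. Units with zero census population (ln undefined) or with a
#' flagged-missing zonal statistic in any covariate are dropped with a
#' message.
#'
#' @param stack a [CovariateStack-class].
#' @param admin an aligned [AdminLayer-class] with census at \code{level}.
#' @param level census level driving the model (default \code{"county"}).
#' @return \code{data.frame(unit_id, ntl, ndvi_max, elevation, slope, guf,
#'   poi_den, y)}.
#' @export
buildTrainingTable <- function(stack, admin, level = "county") {
  stopifnot(is(stack, "CovariateStack"), is(admin, "AdminLayer"))
  stopIfMisaligned(stack@spec, admin@labels@spec, "stack and admin layer")
  u <- censusAt(admin, level)
  labels <- labelRaster(admin, level)
  feats <- lapply(stack@layers, function(r) zonalAggregate(r, labels, "mean"))
  ids <- feats[[1]]$unit_id
  tab <- data.frame(unit_id = ids)
  for (nm in names(feats))
    tab[[nm]] <- feats[[nm]]$value[match(ids, feats[[nm]]$unit_id)]
  m <- match(tab$unit_id, u$unit_id)
  dens <- u$census_pop[m] / u$area_km2[m]
  tab$y <- log(dens)
  dropMissing <- rowSums(is.na(tab[, covariateNames(), drop = FALSE])) > 0
  dropZero <- !is.finite(tab$y)
  if (any(dropMissing))
    message(sum(dropMissing), " unit(s) dropped: missing covariate zonal statistic")
  if (any(dropZero))
    message(sum(dropZero), " unit(s) dropped: zero census population")
  tab <- tab[!dropMissing & !dropZero, , drop = FALSE]
  if (!nrow(tab)) stop("no usable training units at level ", level,
                       call. = FALSE)
  row.names(tab) <- NULL
  tab
}

#' Turn a prediction layer into a dasymetric weight raster
#'
#' \code{mode = "exp"} back-transforms the ln-density prediction to the
#' density scale (\code{W = exp(pred)}), the standard dasymetric choice
#' and the package default. \code{mode = "raw"} uses the ln prediction
#' itself, clipped at zero, as the weight — provided because published
#' weight-layer value ranges in this literature coincide with ln-prediction
#' ranges, implying raw ln weights were used. Because redistribution
#' divides by the per-county weight sum, the two modes differ only in the
#' relative within-county allocation, never in the county totals.
#'
#' @param pred [GeoRaster-class] of predicted ln density.
#' @param mode \code{"exp"} (default) or \code{"raw"}.
#' @return [GeoRaster-class] of non-negative weights; nodata mask
#'   retained.
#' @export
weightsFromPrediction <- function(pred, mode = c("exp", "raw")) {
  mode <- match.arg(mode)
  stopifnot(is(pred, "GeoRaster"))
  v <- pred@values
  if (any(is.infinite(v) & v < 0, na.rm = TRUE))
    stop("prediction contains -Inf; cannot form weights", call. = FALSE)
  w <- if (mode == "exp") exp(v) else pmax(v, 0)
  out <- geoRaster(w, pred@spec, nodata = pred@nodata)
  attr(out, "mode") <- mode
  out
}

#' Redistribute census counts onto the grid (dasymetric mapping)
#'
#' Allocates each unit's census count across its valid grid cells in
#' proportion to the weight raster:
#' \deqn{POP_{grid} = POP_{county} \times W_{grid} / W_{county},}
#' with \eqn{W_{county}} the sum of weights over the unit's valid cells.
#' Mass is conserved exactly: per-unit grid sums equal the census to
#' floating-point precision, whatever the weights. A unit whose weights
#' sum to zero falls back to uniform allocation over its valid cells (with
#' a warning); a unit with census population but no valid cells is an
#' error.
#'
#' @param W weight raster from [weightsFromPrediction()].
#' @param admin an aligned [AdminLayer-class] with census at \code{level}.
#' @param level census level to redistribute (default \code{"county"}).
#' @return [GeoRaster-class] of persons per cell (nodata outside the valid
#'   allocation domain).
#' @export
redistribute <- function(W, admin, level = "county") {
  stopifnot(is(W, "GeoRaster"), is(admin, "AdminLayer"))
  stopIfMisaligned(W@spec, admin@labels@spec, "weights and admin layer")
  u <- censusAt(admin, level)
  labels <- labelRaster(admin, level)
  l <- as.vector(labels@values)
  w <- as.vector(W@values)
  valid <- !is.na(w) & !is.na(l) & l != 0
  out <- rep(NA_real_, length(w))
  wsum <- rowsum(w[valid], l[valid])
  ncell <- rowsum(rep(1, sum(valid)), l[valid])
  noCells <- !(u$unit_id %in% as.numeric(rownames(wsum)))
  if (any(noCells & !is.na(u$census_pop) & u$census_pop > 0))
    stop("unit(s) ", paste(u$unit_id[noCells & u$census_pop > 0],
                           collapse = ", "),
         " have census population but no valid cells", call. = FALSE)
  key <- match(as.character(l[valid]), rownames(wsum))
  pop <- u$census_pop[match(l[valid], u$unit_id)]
  ws <- wsum[key, 1]
  alloc <- ifelse(ws > 0, pop * w[valid] / ws, pop / ncell[key, 1])
  out[valid] <- alloc
  nZero <- sum(wsum[, 1] == 0 & ncell[, 1] > 0)
  if (nZero > 0)
    warning(nZero, " unit(s) had all-zero weights; ",
            "census allocated uniformly over their valid cells")
  geoRaster(matrix(out, W@spec@nRows, W@spec@nCols), W@spec,
            nodata = W@nodata)
}
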