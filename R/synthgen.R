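#' @include AllClasses.R AllGenerics.R utils.R geodata-raster.R geodata-zonal.R
NULL

#' Default per-category POI rates
#'
#' Twenty per-capita point rates spanning roughly three orders of
#' magnitude, mirroring the very uneven real-world distribution of POI
#' category counts (from a few hundred airports to hundreds of thousands
#' of retail points, per ~1e9 persons).
#'
#' @return numeric vector of length 20 (points per person).
#' @export
defaultPoiRates <- function() {
  exp(seq(log(2e-6), log(4.5e-4), length.out = 20))
}

#' Configure a synthetic coastal scene
#'
#' Builds a [SceneConfig-class] with the package's study-condition
#' defaults: a 512 x 512 grid of 100 m cells, a sea strip on the west,
#' 80 counties of 5 townships nested in 4 provinces, 25 settlement blobs,
#' a log-linear true density model with ln-noise 0.3, 2 million residents
#' and POI rates that together place roughly 2 points per 1000 persons.
#' Rationale for each default is in the methods vignette.
#'
#' @param nRows,nCols,cellSize,crsTag grid geometry (see [GridSpec()]).
#' @param seed RNG seed; the whole scene is deterministic in it.
#' @param nProvinces,nCounties,townshipsPerCounty admin partition sizes.
#' @param nSettlements number of Gaussian settlement intensity blobs.
#' @param beta length-6 coefficients of the true ln-density model on the
#'   standardized covariates (ntl, ndvi, elevation, slope, guf,
#'   poi-proxy).
#' @param settlementBoost ln-density gain per unit normalized settlement
#'   intensity.
#' @param noiseSd ln-density noise standard deviation (ln units).
#' @param noiseCorrLength correlation length of the ln-density noise (m).
#' @param totalPop total scene population (persons).
#' @param poiRatePerCapita length-20 per-category POI rates
#'   (points/person); see [defaultPoiRates()].
#' @param ntlBloomingRadius nighttime-light blooming radius (m).
#' @param coastFraction fraction of the domain that is sea (west strip).
#' @param elevGradient mean elevation rise with distance from coast (m/m).
#' @param elevNoiseSd smooth elevation noise SD (m).
#' @param settlementSigmaRange settlement blob radius range as a fraction
#'   of the larger grid dimension.
#' @return a validated [SceneConfig-class].
#' @export
sceneConfig <- function(nRows = 512, nCols = 512, cellSize = 100,
                        crsTag = "local-metric", seed = 1,
                        nProvinces = 4, nCounties = 80,
                        townshipsPerCounty = 5, nSettlements = 25,
                        beta = c(ntl = 0.3, ndvi = -0.25, elevation = -0.2,
                                 slope = -0.15, guf = 0.25, poi = 0.5),
                        settlementBoost = 1.0, noiseSd = 0.3,
                        noiseCorrLength = 1000,
                        totalPop = 2e6,
                        poiRatePerCapita = defaultPoiRates(),
                        ntlBloomingRadius = 1000, coastFraction = 0.3,
                        elevGradient = 8e-4, elevNoiseSd = 3,
                        settlementSigmaRange = c(0.05, 0.12)) {
  new("SceneConfig",
      spec = GridSpec(nRows, nCols, cellSize = cellSize, crsTag = crsTag),
      seed = as.integer(seed), nProvinces = as.integer(nProvinces),
      nCounties = as.integer(nCounties),
      townshipsPerCounty = as.integer(townshipsPerCounty),
      nSettlements = as.integer(nSettlements),
      beta = as.numeric(beta), settlementBoost = as.numeric(settlementBoost),
      noiseSd = as.numeric(noiseSd),
      noiseCorrLength = as.numeric(noiseCorrLength),
      totalPop = as.numeric(totalPop),
      poiRatePerCapita = as.numeric(poiRatePerCapita),
      ntlBloomingRadius = as.numeric(ntlBloomingRadius),
      coastFraction = as.numeric(coastFraction),
      elevGradient = as.numeric(elevGradient),
      elevNoiseSd = as.numeric(elevNoiseSd),
      settlementSigmaRange = as.numeric(settlementSigmaRange))
}

# z-standardize a matrix over a logical mask
zstd <- function(m, mask) {
  v <- m[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  (m - mean(v)) / s
}

#' Generate a seeded synthetic coastal scene
#'
#' Deterministically constructs a full scene from a [SceneConfig-class]:
#' sea strip and coast distances, an elevation ramp with smoothed noise and
#' its slope, settlement intensity blobs biased towards low elevation, the
#' observable covariates (blooming nighttime light, 36 ten-day NDVI images
#' suppressed by built-up fraction, thresholded settlement footprint), a
#' true population surface whose ln density is log-linear in the
#' covariates plus a settlement term and Gaussian noise, per-category POI
#' points drawn from an inhomogeneous Poisson field with intensity
#' proportional to true population, and a nested Voronoi admin partition
#' whose census counts are exact zonal sums of the true surface.
#'
#' @param config a [SceneConfig-class].
#' @return a [Scene-class].
#' @export
generateScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  set.seed(config@seed)
  spec <- config@spec
  nr <- spec@nRows; nc <- spec@nCols
  cs <- spec@cellSize

  # (1) sea strip on the west, distance to coast, elevation ramp + noise
  nSea <- max(1L, round(config@coastFraction * nc))
  if (nSea >= nc) stop("coastFraction leaves no land", call. = FALSE)
  land <- matrix(1, nr, nc); land[, seq_len(nSea)] <- 0
  landMask <- geoRaster(land, spec)
  landIdx <- which(land == 1)
  dist <- distanceToCoast(landMask)
  noise <- gaussianBlur(matrix(stats::rnorm(nr * nc), nr, nc),
                        sigma = max(2, 0.01 * max(nr, nc)))
  noise <- noise * (config@elevNoiseSd / stats::sd(noise))
  elev <- dist@values * config@elevGradient + noise
  elev[land == 1] <- pmax(elev[land == 1], 0)
  elev[land == 0] <- 0
  elevation <- geoRaster(elev, spec)
  slope <- slopeFromDem(elevation)

  # (2) settlements biased toward low elevation
  nS <- config@nSettlements
  if (length(landIdx) < max(nS, config@nCounties))
    stop("fewer land cells than requested settlements/counties", call. = FALSE)
  prob <- exp(-elev[landIdx] / 20)
  centers <- sample(landIdx, nS, prob = prob)
  amp <- stats::rlnorm(nS, 0, 0.5)
  sig <- stats::runif(nS, config@settlementSigmaRange[1],
                      config@settlementSigmaRange[2]) * max(nr, nc)
  rowIx <- matrix(seq_len(nr), nr, nc)
  colIx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  intensity <- matrix(0, nr, nc)
  for (s in seq_len(nS)) {
    r0 <- (centers[s] - 1) %% nr + 1
    c0 <- (centers[s] - 1) %/% nr + 1
    d2 <- (rowIx - r0)^2 + (colIx - c0)^2
    intensity <- intensity + amp[s] * exp(-d2 / (2 * sig[s]^2))
  }
  intensity[land == 0] <- 0
  intNorm <- intensity / max(intensity)

  # (4, observables) settlement footprint, NDVI series, blooming NTL
  guf <- geoRaster((intNorm > 0.1) * 1, spec)
  builtFrac <- pmin(1, intNorm * 1.5)
  ndviSeries <- vector("list", 36)
  for (t in 1:36) {
    seasonal <- 0.25 + 0.35 * (1 + sin(2 * pi * t / 36 - pi / 2)) / 2
    img <- seasonal * (1 - 0.8 * builtFrac) +
      matrix(stats::rnorm(nr * nc, 0, 0.04), nr, nc)
    img[land == 0] <- -0.1
    ndviSeries[[t]] <- geoRaster(pmin(pmax(img, -1), 1), spec)
  }
  ntlRaw <- gaussianBlur(intensity, config@ntlBloomingRadius / cs)
  ntl <- geoRaster(63 * ntlRaw / max(ntlRaw), spec)

  # (3) true ln density: log-linear in covariates + settlement term + noise.
  # The noise is spatially correlated so that, like real unexplained
  # density variation, it does not average out at validation-unit scale.
  # the field is always drawn so that scenes with the same seed share all
  # other components whatever noiseSd is (paired comparisons across levels)
  lnNoise <- gaussianBlur(matrix(stats::rnorm(nr * nc), nr, nc),
                          sigma = config@noiseCorrLength / cs)
  lnNoise <- lnNoise * (config@noiseSd / stats::sd(lnNoise))
  ndviMaxTrue <- 0.6 * (1 - 0.8 * builtFrac)
  b <- config@beta
  lnD <- b[1] * zstd(ntl@values, land == 1) +
    b[2] * zstd(ndviMaxTrue, land == 1) +
    b[3] * zstd(elev, land == 1) +
    b[4] * zstd(slope@values, land == 1) +
    b[5] * guf@values +
    b[6] * zstd(intNorm, land == 1) +
    config@settlementBoost * intNorm +
    lnNoise
  dens <- exp(lnD)
  dens[land == 0] <- 0
  popVals <- dens * (config@totalPop / sum(dens[landIdx]))
  popM <- popVals
  popM[land == 0] <- NA_real_
  truePop <- geoRaster(popM, spec)

  # (5) POIs: inhomogeneous Poisson, intensity = rate_k * truePop per cell
  pois <- generatePois(truePop, config, landIdx)

  # (6) nested Voronoi admin partition with exact census sums
  admin <- generateAdmin(spec, land, landIdx, config)
  admin <- aggregateCensus(truePop, admin)

  new("Scene", ntl = ntl, ndviSeries = ndviSeries, elevation = elevation,
      slope = slope, guf = guf, truePop = truePop, admin = admin,
      pois = pois, landMask = landMask, config = config)
}

generatePois <- function(truePop, config, landIdx) {
  spec <- truePop@spec
  nr <- spec@nRows
  pop <- truePop@values[landIdx]
  xs <- spec@originX + ((landIdx - 1) %/% nr + 0.5) * spec@cellSize
  ys <- spec@originY - ((landIdx - 1) %% nr + 0.5) * spec@cellSize
  out <- vector("list", 20)
  for (k in 1:20) {
    lam <- config@poiRatePerCapita[k] * pop
    n <- stats::rpois(length(lam), lam)
    tot <- sum(n)
    if (tot == 0) next
    rep_ix <- rep.int(seq_along(lam), n)
    out[[k]] <- data.frame(
      x = xs[rep_ix] + stats::runif(tot, -0.5, 0.5) * spec@cellSize,
      y = ys[rep_ix] + stats::runif(tot, -0.5, 0.5) * spec@cellSize,
      category = k
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(x = numeric(), y = numeric(),
                                      category = integer())
  row.names(res) <- NULL
  res
}

# nearest-seed Voronoi assignment of `cells` (linear indices) to seeds
voronoiAssign <- function(cells, seeds, nr) {
  rs <- (cells - 1) %% nr + 1; csx <- (cells - 1) %/% nr + 1
  sr <- (seeds - 1) %% nr + 1; sc <- (seeds - 1) %/% nr + 1
  best <- rep.int(Inf, length(cells))
  who <- integer(length(cells))
  for (s in seq_along(seeds)) {
    d2 <- (rs - sr[s])^2 + (csx - sc[s])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    who[upd] <- s
  }
  who
}

generateAdmin <- function(spec, land, landIdx, config) {
  nr <- spec@nRows
  nP <- config@nProvinces; nC <- config@nCounties
  if (length(landIdx) < nC)
    stop("fewer land cells than requested counties", call. = FALSE)
  provSeeds <- sample(landIdx, nP)
  ctySeeds <- sample(landIdx, nC)
  ctyOfCell <- voronoiAssign(landIdx, ctySeeds, nr)
  provOfCty <- voronoiAssign(ctySeeds, provSeeds, nr)
  provIds <- seq_len(nP)
  ctyIds <- nP + seq_len(nC)
  labels <- matrix(0, nr, spec@nCols)
  units <- list(data.frame(unit_id = provIds, level = "province",
                           parent_id = 0L, census_pop = NA_real_,
                           area_km2 = NA_real_),
                data.frame(unit_id = ctyIds, level = "county",
                           parent_id = provIds[provOfCty],
                           census_pop = NA_real_, area_km2 = NA_real_))
  nextTwp <- nP + nC
  twpRows <- list()
  for (ci in seq_len(nC)) {
    cells <- landIdx[ctyOfCell == ci]
    if (!length(cells)) next
    nT <- min(config@townshipsPerCounty, length(cells))
    tSeeds <- if (nT == 1L) cells[1L] else sample(cells, nT)
    tw <- voronoiAssign(cells, tSeeds, nr)
    ids <- nextTwp + seq_len(nT)
    nextTwp <- nextTwp + nT
    labels[cells] <- ids[tw]
    twpRows[[ci]] <- data.frame(unit_id = ids, level = "township",
                                parent_id = ctyIds[ci],
                                census_pop = NA_real_, area_km2 = NA_real_)
  }
  units <- do.call(rbind, c(units, twpRows))
  # drop childless units (counties with no cells, provinces with no county;
  # possible when seeds coincide or a province seed wins no county)
  keep <- units$level != "county" |
    units$unit_id %in% units$parent_id[units$level == "township"]
  units <- units[keep, , drop = FALSE]
  keep <- units$level != "province" |
    units$unit_id %in% units$parent_id[units$level == "county"]
  units <- units[keep, , drop = FALSE]
  adminLayer(geoRaster(labels, spec), units)
}

#' Populate census counts from a population surface
#'
#' Sets \code{census_pop} at every admin level to the exact zonal sum of
#' the population raster, so county censuses equal the sum of their
#' townships' censuses by construction. A township whose label is missing
#' from the unit table is an error.
#'
#' @param truePop [GeoRaster-class] of persons per cell.
#' @param admin an [AdminLayer-class] aligned with \code{truePop}.
#' @return the [AdminLayer-class] with census counts filled in.
#' @export
aggregateCensus <- function(truePop, admin) {
  stopifnot(is(truePop, "GeoRaster"), is(admin, "AdminLayer"))
  stopIfMisaligned(truePop@spec, admin@labels@spec,
                   "population raster and admin labels")
  u <- admin@units
  lab <- admin@labels@values
  present <- unique(lab[!is.na(lab) & lab != 0])
  if (!all(present %in% u$unit_id[u$level == "township"]))
    stop("label raster contains ids missing from the unit table",
         call. = FALSE)
  z <- zonalAggregate(truePop, admin@labels, "sum")
  twpPop <- z$value[match(u$unit_id, z$unit_id)]
  sel <- u$level == "township"
  u$census_pop[sel] <- twpPop[sel]
  u$census_pop[sel][is.na(u$census_pop[sel])] <- 0
  twp <- u[u$level == "township", ]
  ctySum <- rowsum(twp$census_pop, twp$parent_id)
  sel <- u$level == "county"
  u$census_pop[sel] <- ctySum[match(as.character(u$unit_id[sel]),
                                    rownames(ctySum)), 1]
  u$census_pop[sel][is.na(u$census_pop[sel])] <- 0
  cty <- u[sel, ]
  prvSum <- rowsum(cty$census_pop, cty$parent_id)
  selp <- u$level == "province"
  u$census_pop[selp] <- prvSum[match(as.character(u$unit_id[selp]),
                                     rownames(prvSum)), 1]
  u$census_pop[selp][is.na(u$census_pop[selp])] <- 0
  out <- admin
  out@units <- u
  out
}

setMethod("show", "Scene", function(object) {
  cfg <- object@config
  cat(sprintf("Scene: %d x %d grid (%g m cells), seed %d\n",
              cfg@spec@nRows, cfg@spec@nCols, cfg@spec@cellSize, cfg@seed))
  cat(sprintf("  population: %.0f persons on %d land cells; %d POIs in %d categories\n",
              sum(object@truePop@values, na.rm = TRUE),
              sum(object@landMask@values == 1),
              nrow(object@pois), length(unique(object@pois$category))))
  show(object@admin)
})
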