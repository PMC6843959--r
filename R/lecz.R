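#' @include AllClasses.R AllGenerics.R utils.R geodata-zonal.R
NULL

#' Extract the low-elevation coastal zone mask
#'
#' Three-step overlay: a land cell belongs to the LECZ iff its elevation is
#' strictly below \code{elevThreshold} and its distance to the coast is
#' strictly below \code{distThreshold} (strict inequalities, following the
#' zone's definitional wording; a cell at exactly 10 m is excluded).
#' Nodata DEM cells are excluded from the mask and logged. With
#' \code{connectivity = TRUE} only mask components 8-connected to the
#' coast are kept, enforcing the "contiguous area along the coast" clause;
#' the default reproduces the plain overlay, which does not.
#'
#' @param dem [GeoRaster-class] of elevation (m).
#' @param dist [GeoRaster-class] of distance to coast (m), e.g. from
#'   [distanceToCoast()].
#' @param landMask [GeoRaster-class], 1 on land and 0 at sea.
#' @param elevThreshold elevation cut in metres (default 10).
#' @param distThreshold distance cut in metres (default 100000).
#' @param connectivity keep only components 8-connected to the coast
#'   (default FALSE).
#' @return [GeoRaster-class] mask, 1 inside the LECZ and 0 outside.
#' @export
extractLecz <- function(dem, dist, landMask, elevThreshold = 10,
                        distThreshold = 100000, connectivity = FALSE) {
  stopifnot(is(dem, "GeoRaster"), is(dist, "GeoRaster"),
            is(landMask, "GeoRaster"))
  if (elevThreshold <= 0 || distThreshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  stopIfMisaligned(dem@spec, dist@spec, "DEM and distance rasters")
  stopIfMisaligned(dem@spec, landMask@spec, "DEM and land mask")
  e <- dem@values
  nBad <- sum(is.na(e) & landMask@values == 1)
  if (nBad > 0)
    message(nBad, " nodata DEM cell(s) excluded from the LECZ mask")
  m <- (landMask@values == 1) & !is.na(e) & (e < elevThreshold) &
    (dist@values < distThreshold)
  m[is.na(m)] <- FALSE
  if (connectivity) {
    sea <- landMask@values == 0
    # seed: mask cells 8-adjacent to a sea cell, then flood-fill inside mask
    seed <- m & dilate8(sea)
    m <- floodFill8(seed, m)
  }
  geoRaster(m * 1, dem@spec)
}

# one 8-neighbourhood dilation step
dilate8 <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    out <- out | b[rs, cs, drop = FALSE]
  }
  out
}

# grow `seed` within `domain` until fixpoint (8-connectivity)
floodFill8 <- function(seed, domain) {
  cur <- seed & domain
  repeat {
    nxt <- dilate8(cur) & domain
    if (sum(nxt) == sum(cur)) return(cur)
    cur <- nxt
  }
}

#' Exposed population per administrative region
#'
#' Overlays a population grid with the LECZ mask and reports, per region
#' at the chosen level plus a global row (\code{region_id = 0}): the
#' exposed population (sum inside the mask), the total population and the
#' exposed percentage. A region with zero total population gets a flagged
#' \code{NA} percentage, not 0.
#'
#' @param pop [GeoRaster-class] of persons per cell.
#' @param mask LECZ mask from [extractLecz()].
#' @param admin an aligned [AdminLayer-class].
#' @param level reporting level (default \code{"province"}).
#' @return \code{data.frame(region_id, exposed_pop, total_pop,
#'   pct_exposed)}; the first row is the global total.
#' @export
exposureTable <- function(pop, mask, admin, level = "province") {
  stopifnot(is(pop, "GeoRaster"), is(mask, "GeoRaster"),
            is(admin, "AdminLayer"))
  stopIfMisaligned(pop@spec, mask@spec, "population and mask rasters")
  stopIfMisaligned(pop@spec, admin@labels@spec, "population and admin layer")
  labels <- labelRaster(admin, level)
  masked <- geoRaster(pop@values * (mask@values != 0), pop@spec)
  tot <- zonalAggregate(pop, labels, "sum")
  exp_ <- zonalAggregate(masked, labels, "sum")
  ids <- tot$unit_id
  total <- tot$value
  exposed <- exp_$value[match(ids, exp_$unit_id)]
  total[is.na(total)] <- 0
  exposed[is.na(exposed)] <- 0
  pct <- ifelse(total > 0, 100 * exposed / total, NA_real_)
  out <- data.frame(region_id = ids, exposed_pop = exposed,
                    total_pop = total, pct_exposed = pct)
  globalTot <- sum(total)
  globalExp <- sum(exposed)
  rbind(data.frame(region_id = 0, exposed_pop = globalExp,
                   total_pop = globalTot,
                   pct_exposed = if (globalTot > 0)
                     100 * globalExp / globalTot else NA_real_),
        out)
}
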