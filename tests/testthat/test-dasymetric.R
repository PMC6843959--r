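# training-table assembly, weight construction and mass-preserving
# redistribution

# a hand-built 2-county admin layer over a 2x4 grid (left half county 10,
# right half county 11; one township per county)
handAdmin <- function(censusL = 100, censusR = 60) {
  labels <- geoRaster(matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), 2, 4))
  units <- data.frame(
    unit_id = c(90L, 10L, 11L, 1L, 2L),
    level = c("province", "county", "county", "township", "township"),
    parent_id = c(0L, 90L, 90L, 10L, 11L),
    census_pop = c(censusL + censusR, censusL, censusR, censusL, censusR),
    area_km2 = NA_real_)
  adminLayer(labels, units)
}

test_that("training target is ln census density and features are zonal means", {
  sc <- tinyScene(seed = 8)
  stack <- quietStack(sc)
  tab <- suppressMessages(buildTrainingTable(stack, sc@admin, "county"))
  u <- adminUnits(sc@admin, "county")
  m <- match(tab$unit_id, u$unit_id)
  expect_equal(tab$y, log(u$census_pop[m] / u$area_km2[m]))
  lab <- labelRaster(sc@admin, "county")
  for (nm in c("ntl", "poi_den")) {
    o <- oracleZonal(rasterValues(stackLayers(stack)[[nm]]),
                     rasterValues(lab), "mean")
    expect_equal(tab[[nm]], o$value[match(tab$unit_id, o$unit_id)])
  }
})

test_that("a unit with pop 1000 over 10 km2 gets y = ln(100)", {
  adm <- handAdmin(censusL = 1000, censusR = 500)
  # 2x4 grid of 100 m cells: each county covers 4 cells = 0.04 km2; build a
  # bigger-cell grid so the left county is exactly 10 km2
  spec <- GridSpec(2, 4, cellSize = sqrt(10 / 4) * 1000)
  labels <- geoRaster(matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), 2, 4), spec)
  units <- adminUnits(adm)
  adm2 <- adminLayer(labels, units)
  mkLayer <- function(x) geoRaster(matrix(x, 2, 4), spec)
  layers <- list(ntl = mkLayer(1), ndvi_max = mkLayer(0.5),
                 elevation = mkLayer(5), slope = mkLayer(1),
                 guf = mkLayer(0), poi_den = mkLayer(0.1))
  stack <- new("CovariateStack", layers = layers, spec = spec,
               metadata = list())
  tab <- buildTrainingTable(stack, adm2, "county")
  expect_equal(tab$y[tab$unit_id == 10], log(100), tolerance = 1e-12)
})

test_that("units with a fully-nodata covariate or zero census are dropped with a log entry", {
  adm <- handAdmin(censusL = 100, censusR = 0)
  spec <- gridSpec(adm@labels)
  mkLayer <- function(x) geoRaster(matrix(x, 2, 4), spec)
  ntl <- matrix(1, 2, 4); ntl[, 1:2] <- NA    # county 10 fully nodata in ntl
  layers <- list(ntl = geoRaster(ntl, spec), ndvi_max = mkLayer(0.5),
                 elevation = mkLayer(5), slope = mkLayer(1),
                 guf = mkLayer(0), poi_den = mkLayer(0.1))
  stack <- new("CovariateStack", layers = layers, spec = spec,
               metadata = list())
  expect_message(expect_error(buildTrainingTable(stack, adm, "county"),
                              "no usable"),
                 "missing covariate")
})

test_that("weight construction: exp back-transform, raw passthrough, monotone in both modes", {
  pred <- geoRaster(matrix(c(0, 1, 2, -1), 2, 2))
  wExp <- rasterValues(weightsFromPrediction(pred, "exp"))
  expect_equal(wExp, exp(rasterValues(pred)))
  expect_equal(wExp[1, 1], 1)
  wRaw <- rasterValues(weightsFromPrediction(pred, "raw"))
  expect_equal(wRaw, matrix(c(0, 1, 2, 0), 2, 2))
  # monotone: a > b implies W(a) >= W(b), strict where not clipped
  expect_true(all(order(wExp) == order(rasterValues(pred))))
  bad <- geoRaster(matrix(c(-Inf, 0, 0, 0), 2, 2))
  expect_error(weightsFromPrediction(bad, "exp"), "-Inf")
})

test_that("redistribution follows the weight ratios exactly on hand examples", {
  adm <- handAdmin(censusL = 100, censusR = 60)
  w <- geoRaster(matrix(c(1, 3, 0, 0, 2, 2, 2, 2), 2, 4))
  # county 10: cells (1,3) weights on first column pair; county 11 uniform
  pop <- rasterValues(suppressWarnings(redistribute(w, adm, "county")))
  expect_equal(pop[1, 1], 100 * 1 / 4)
  expect_equal(pop[2, 1], 100 * 3 / 4)
  expect_equal(pop[, 3:4], matrix(15, 2, 2))  # 60 over 4 equal weights
  # linearity: doubling census doubles every cell
  adm2 <- handAdmin(censusL = 200, censusR = 120)
  pop2 <- rasterValues(suppressWarnings(redistribute(w, adm2, "county")))
  expect_equal(pop2, 2 * pop)
})

test_that("all-zero weights fall back to uniform allocation with a warning", {
  adm <- handAdmin(censusL = 60, censusR = 60)
  w <- geoRaster(matrix(c(0, 0, 0, NA, 1, 1, 1, 1), 2, 4))
  expect_warning(pop <- redistribute(w, adm, "county"), "uniformly")
  v <- rasterValues(pop)
  expect_equal(v[cbind(c(1, 2, 1), c(1, 1, 2))], rep(20, 3))  # 60 over 3 valid
  expect_true(is.na(v[2, 2]))                                  # nodata retained
})

test_that("a unit with census but no valid cells is an error", {
  adm <- handAdmin(censusL = 100, censusR = 60)
  w <- geoRaster(matrix(c(1, 1, 1, 1, NA, NA, NA, NA), 2, 4))
  expect_error(redistribute(w, adm, "county"), "no valid cells")
})

test_that("mass conservation and weight-scale invariance hold on generated scenes", {
  sc <- tinyScene(seed = 9)
  stack <- quietStack(sc)
  tab <- suppressMessages(buildTrainingTable(stack, sc@admin, "county"))
  rf <- fitRandomForest(tab, nTrees = 100, seed = 6, nRepeats = 1)
  pred <- predictRaster(rf, stack)
  u <- adminUnits(sc@admin, "county")
  for (mode in c("exp", "raw")) {
    W <- weightsFromPrediction(pred, mode)
    pop <- quietRedistribute(W, sc@admin)
    z <- zonalAggregate(pop, labelRaster(sc@admin, "county"), "sum")
    cen <- u$census_pop[match(z$unit_id, u$unit_id)]
    expect_lt(max(abs(z$value - cen) / pmax(cen, 1)), 1e-9)
    # global conservation
    expect_equal(sum(rasterValues(pop), na.rm = TRUE), sum(cen),
                 tolerance = 1e-12)
    # scaling all weights by c > 0 changes nothing (ratio in the formula)
    W2 <- geoRaster(rasterValues(W) * 37.5, gridSpec(W))
    pop2 <- quietRedistribute(W2, sc@admin)
    expect_equal(rasterValues(pop2), rasterValues(pop), tolerance = 1e-12)
  }
})

test_that("re-aggregation reproduces county census exactly but not township census", {
  sc <- tinyScene(seed = 10)
  stack <- quietStack(sc)
  tab <- suppressMessages(buildTrainingTable(stack, sc@admin, "county"))
  rf <- fitRandomForest(tab, nTrees = 100, seed = 7, nRepeats = 1)
  pop <- quietRedistribute(weightsFromPrediction(predictRaster(rf, stack)),
                           sc@admin)
  zc <- zonalAggregate(pop, labelRaster(sc@admin, "county"), "sum")
  uc <- adminUnits(sc@admin, "county")
  expect_equal(zc$value, uc$census_pop[match(zc$unit_id, uc$unit_id)],
               tolerance = 1e-9)
  zt <- zonalAggregate(pop, labelRaster(sc@admin, "township"), "sum")
  ut <- adminUnits(sc@admin, "township")
  # the township gap is what validation measures: not all sums can match
  expect_gt(max(abs(zt$value - ut$census_pop[match(zt$unit_id, ut$unit_id)])),
            1)
})
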