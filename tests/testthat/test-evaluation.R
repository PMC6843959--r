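# held-out accuracy metrics, density-stratified diagnostics, POI ablation

# admin with k townships of one cell each on a 1xk grid (1 county)
rowAdmin <- function(census) {
  k <- length(census)
  labels <- geoRaster(matrix(seq_len(k), 1, k))
  units <- data.frame(
    unit_id = c(900L, 800L, seq_len(k)),
    level = c("province", "county", rep("township", k)),
    parent_id = c(0L, 900L, rep(800L, k)),
    census_pop = c(sum(census), sum(census), census),
    area_km2 = NA_real_)
  adminLayer(labels, units)
}

test_that("a perfect prediction scores zero errors and unit log-R2", {
  adm <- rowAdmin(c(100, 200, 400, 800, 50))
  pop <- geoRaster(matrix(c(100, 200, 400, 800, 50), 1, 5))
  ev <- evaluatePopulation(pop, adm, "township")
  expect_equal(ev$mae, 0)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$mre_pct, 0)
  expect_equal(ev$r2_log, 1)
  expect_equal(ev$n_units, 5)
  expect_equal(ev$n_excluded, 0)
})

test_that("metrics match the hand-computed three-unit example", {
  adm <- rowAdmin(c(100, 200, 400))
  pop <- geoRaster(matrix(c(110, 180, 460), 1, 3))
  ev <- evaluatePopulation(pop, adm, "township")
  expect_equal(ev$mae, 30)
  expect_equal(ev$mre_pct, 100 * (10 / 100 + 20 / 200 + 60 / 400) / 3,
               tolerance = 1e-12)          # 11.666...%
  expect_equal(ev$rmse, sqrt((10^2 + 20^2 + 60^2) / 3), tolerance = 1e-12)
  expect_equal(ev$mean, mean(c(110, 180, 460)))
  expect_equal(ev$pct_rmse, 100 * ev$rmse / mean(c(100, 200, 400)))
})

test_that("uniform overestimation doubles MRE but leaves log-R2 at one", {
  cen <- c(100, 200, 400, 800, 1600)
  adm <- rowAdmin(cen)
  pop <- geoRaster(matrix(2 * cen, 1, 5))
  ev <- evaluatePopulation(pop, adm, "township")
  expect_equal(ev$mre_pct, 100)
  expect_equal(ev$r2_log, 1)
})

test_that("evaluation is invariant to unit ordering and to density rescaling", {
  sc <- tinyScene(seed = 13)
  stack <- quietStack(sc)
  tab <- suppressMessages(buildTrainingTable(stack, sc@admin, "county"))
  rf <- fitRandomForest(tab, nTrees = 100, seed = 9, nRepeats = 1)
  pop <- quietRedistribute(weightsFromPrediction(predictRaster(rf, stack)),
                           sc@admin)
  ev <- evaluatePopulation(pop, sc@admin, "township")
  # shuffle the unit table rows
  shuffled <- sc@admin
  set.seed(1)
  shuffled@units <- shuffled@units[sample(nrow(shuffled@units)), ]
  ev2 <- evaluatePopulation(pop, shuffled, "township")
  expect_equal(ev2$mae, ev$mae)
  expect_equal(ev2$r2_log, ev$r2_log)
  # r2 on log densities is unchanged by any positive rescale of both grids
  scaled <- sc@admin
  scaled@units$census_pop <- scaled@units$census_pop * 3.7
  pop3 <- geoRaster(rasterValues(pop) * 3.7, gridSpec(pop))
  ev3 <- evaluatePopulation(pop3, scaled, "township")
  expect_equal(ev3$r2_log, ev$r2_log, tolerance = 1e-12)
})

test_that("zero-census units are excluded from ratio metrics and counted", {
  adm <- rowAdmin(c(100, 0, 400))
  pop <- geoRaster(matrix(c(110, 5, 380), 1, 3))
  ev <- evaluatePopulation(pop, adm, "township")
  expect_equal(ev$n_excluded, 1)
  expect_equal(ev$mre_pct, 100 * (10 / 100 + 20 / 400) / 2, tolerance = 1e-12)
  adm0 <- rowAdmin(c(0, 0))
  expect_error(evaluatePopulation(geoRaster(matrix(1, 1, 2)), adm0,
                                  "township"),
               "positive census")
})

test_that("stratum membership equals a sort-and-slice oracle; perfect prediction has zero bias", {
  set.seed(42)
  cen <- round(exp(rnorm(40, 5, 1.5)))
  adm <- rowAdmin(cen)
  pop <- geoRaster(matrix(cen * exp(rnorm(40, 0, 0.2)), 1, 40))
  st <- stratifiedReport(pop, adm, "township")
  expect_setequal(st$stratum, c("bottom20", "middle60", "top20"))
  # oracle: ranks from an explicit sort (all areas equal here)
  q <- stats::quantile(cen, c(0.2, 0.8))
  nBottom <- sum(cen <= q[1]); nTop <- sum(cen > q[2])
  expect_equal(st$n[st$stratum == "bottom20"], nBottom)
  expect_equal(st$n[st$stratum == "top20"], nTop)
  expect_equal(sum(st$n), 40)
  # perfect prediction: zero mean signed log error in every stratum
  st0 <- stratifiedReport(geoRaster(matrix(cen, 1, 40)), adm, "township")
  expect_equal(st0$mean_log_error, rep(0, 3))
})

test_that("identical densities collapse to a single flagged stratum", {
  adm <- rowAdmin(rep(100, 10))
  pop <- geoRaster(matrix(rep(101, 10), 1, 10))
  expect_warning(st <- stratifiedReport(pop, adm, "township"), "degenerate")
  expect_equal(nrow(st), 1)
  adm2 <- rowAdmin(c(10, 20, 30))
  expect_error(stratifiedReport(geoRaster(matrix(1:3, 1, 3)), adm2,
                                "township"),
               "fewer than 5")
})

test_that("ablation on a POI-free scene returns identical reports and conserves mass", {
  sc <- generateScene(sceneConfig(nRows = 48, nCols = 48, nCounties = 12,
                                  townshipsPerCounty = 3, nSettlements = 6,
                                  poiRatePerCapita = rep(0, 20), seed = 14))
  ab <- suppressMessages(suppressWarnings(
    ablationCompare(sc, model = "rf", nTrees = 100, seed = 15)))
  expect_equal(ab$with, ab$without, tolerance = 1e-12)
  expect_true(all(abs(ab$diff) < 1e-9))
})

test_that("noisier scenes degrade township accuracy monotonically in expectation", {
  r2At <- function(noiseSd) {
    mean(vapply(1:5, function(seed) {
      sc <- generateScene(sceneConfig(nRows = 96, nCols = 96, nCounties = 20,
                                      townshipsPerCounty = 3,
                                      nSettlements = 8, noiseSd = noiseSd,
                                      seed = seed))
      stack <- quietStack(sc)
      tab <- suppressMessages(buildTrainingTable(stack, sc@admin, "county"))
      rf <- fitRandomForest(tab, nTrees = 150, seed = seed + 50, nRepeats = 1)
      pop <- quietRedistribute(
        weightsFromPrediction(predictRaster(rf, stack)), sc@admin)
      evaluatePopulation(pop, sc@admin, "township")$r2_log
    }, numeric(1)))
  }
  r2 <- c(r2At(0), r2At(0.3), r2At(0.8))
  expect_true(all(diff(r2) < 0))
})
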