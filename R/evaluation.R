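#' @include AllClasses.R AllGenerics.R utils.R dasymetric.R rf.R
NULL

#' Township-level accuracy assessment of a population grid
#'
#' Compares the predicted population of every held-out unit (the zonal sum
#' of the population grid over the unit) with its census count. Reported
#' metrics: the mean predicted count, MRE\% (mean absolute relative
#' error over positive-census units), MAE, RMSE, \%RMSE (RMSE as a
#' percentage of the mean census count) and the squared Pearson
#' correlation of log10 population densities over units with positive
#' census and positive prediction. Units with zero census are excluded
#' from the ratio metrics and counted in \code{n_excluded}.
#'
#' @param pop [GeoRaster-class] of persons per cell.
#' @param admin an aligned [AdminLayer-class] with census at \code{level}.
#' @param level assessment level (default \code{"township"}, the held-out
#'   census level).
#' @return one-row \code{data.frame(mean, mre_pct, mae, rmse, pct_rmse,
#'   r2_log, n_units, n_excluded)}.
#' @export
evaluatePopulation <- function(pop, admin, level = "township") {
  d <- unitPredictions(pop, admin, level)
  P <- d$census; Ph <- d$predicted
  if (!any(P > 0))
    stop("no units with positive census at level ", level, call. = FALSE)
  n <- length(P)
  pos <- P > 0
  err <- Ph - P
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  both <- pos & Ph > 0
  r2 <- if (sum(both) >= 3) {
    stats::cor(log10(P[both] / d$area[both]),
               log10(Ph[both] / d$area[both]))^2
  } else NA_real_
  data.frame(
    mean = mean(Ph),
    mre_pct = 100 * mean(abs(err[pos]) / P[pos]),
    mae = mae,
    rmse = rmse,
    pct_rmse = 100 * rmse / mean(P),
    r2_log = r2,
    n_units = n,
    n_excluded = sum(!pos)
  )
}

# per-unit census, predicted zonal sums and areas at a level
unitPredictions <- function(pop, admin, level) {
  stopifnot(is(pop, "GeoRaster"), is(admin, "AdminLayer"))
  stopIfMisaligned(pop@spec, admin@labels@spec, "population and admin layer")
  u <- censusAt(admin, level)
  labels <- labelRaster(admin, level)
  z <- zonalAggregate(pop, labels, "sum")
  pred <- z$value[match(u$unit_id, z$unit_id)]
  pred[is.na(pred)] <- 0
  list(unit_id = u$unit_id, census = u$census_pop, predicted = pred,
       area = u$area_km2)
}

#' Density-stratified error diagnostics
#'
#' Ranks units by census population density and cuts them at the 20th and
#' 80th percentiles (ties to the lower stratum) into bottom/middle/top
#' strata, reporting per stratum the log-density R-squared and the mean
#' signed log10 error (log10 predicted minus log10 census density). The
#' characteristic dasymetric smoothing bias shows as a negative mean in
#' the top stratum (under-concentration in dense units) and a positive
#' mean in the bottom stratum (spill-over into sparse units). Degenerate
#' input where all units share one density collapses, with a warning, to a
#' single stratum.
#'
#' @param pop [GeoRaster-class] of persons per cell.
#' @param admin an aligned [AdminLayer-class] with census at \code{level}.
#' @param level assessment level (default \code{"township"}).
#' @param quantiles the two density cut points (default \code{c(0.2, 0.8)}).
#' @return \code{data.frame(stratum, n, r2_log, mean_log_error)}.
#' @export
stratifiedReport <- function(pop, admin, level = "township",
                             quantiles = c(0.2, 0.8)) {
  d <- unitPredictions(pop, admin, level)
  keep <- d$census > 0 & d$predicted > 0
  if (sum(keep) < 5)
    stop("fewer than 5 units with positive census and prediction",
         call. = FALSE)
  dens <- d$census[keep] / d$area[keep]
  densHat <- d$predicted[keep] / d$area[keep]
  q <- stats::quantile(dens, quantiles)
  if (q[1] == q[2]) {
    warning("degenerate density distribution; reporting a single stratum")
    strata <- factor(rep("all", length(dens)), levels = "all")
  } else {
    strata <- cut(dens, c(-Inf, q[1], q[2], Inf),
                  labels = c("bottom20", "middle60", "top20"))
  }
  logErr <- log10(densHat) - log10(dens)
  res <- lapply(levels(strata), function(s) {
    sel <- strata == s
    r2 <- if (sum(sel) >= 3 && stats::sd(dens[sel]) > 0 &&
              stats::sd(densHat[sel]) > 0)
      stats::cor(log10(dens[sel]), log10(densHat[sel]))^2 else NA_real_
    data.frame(stratum = s, n = sum(sel), r2_log = r2,
               mean_log_error = mean(logErr[sel]))
  })
  do.call(rbind, res)
}

#' With/without-POI ablation comparison
#'
#' Runs the mapping pipeline twice on the same scene with the same seeds,
#' differing only in whether the POI density composite carries information
#' (the without-POI run replaces it with an all-zero layer, equivalent to
#' fitting on the remaining five covariates). Returns the two township
#' accuracy reports and their differences; a positive \code{mae}
#' difference in \code{$diff} means POIs reduced the error.
#'
#' @param scene a [Scene-class].
#' @param model \code{"rf"} or \code{"m5"}.
#' @param weightMode \code{"exp"} or \code{"raw"}.
#' @param bandwidth POI KDE bandwidth (m).
#' @param nTrees forest size for the \code{"rf"} engine.
#' @param seed fitting seed shared by the two runs.
#' @return list with \code{with}, \code{without} (each a
#'   [evaluatePopulation()] report) and \code{diff} (without minus with:
#'   positive values mean the POI covariate helped).
#' @export
ablationCompare <- function(scene, model = c("rf", "m5"),
                            weightMode = c("exp", "raw"), bandwidth = 2000,
                            nTrees = 500, seed = 1) {
  model <- match.arg(model)
  weightMode <- match.arg(weightMode)
  runOnce <- function(includePoi) {
    stack <- if (includePoi) buildCovariateStack(scene, bandwidth)
             else suppressWarnings(buildCovariateStack(scene, bandwidth,
                                                       includePoi = FALSE))
    tab <- buildTrainingTable(stack, scene@admin, "county")
    fit <- if (model == "rf") fitRandomForest(tab, nTrees = nTrees, seed = seed)
           else fitModelTree(tab)
    pred <- predictRaster(fit, stack)
    W <- weightsFromPrediction(pred, weightMode)
    pop <- redistribute(W, scene@admin, "county")
    evaluatePopulation(pop, scene@admin, "township")
  }
  withPoi <- runOnce(TRUE)
  withoutPoi <- runOnce(FALSE)
  list(with = withPoi, without = withoutPoi,
       diff = withoutPoi[, 1:6] - withPoi[, 1:6])
}
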