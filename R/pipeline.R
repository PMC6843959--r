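#' @include AllClasses.R AllGenerics.R utils.R synthgen.R covariates.R
#' @include dasymetric.R lecz.R evaluation.R
NULL

#' Default run configuration
#'
#' A plain, YAML-serializable list of every tunable the end-to-end run
#' uses, filled with the package defaults (512 x 512 scene, 2000 m KDE
#' bandwidth, 500-tree forest, exponential weight mode, 10 m / 100 km
#' LECZ thresholds). Fields mirror the arguments of [sceneConfig()],
#' [buildCovariateStack()], the two fitting engines,
#' [weightsFromPrediction()] and [extractLecz()].
#'
#' @param seed master seed; every random stage derives its seed from it.
#' @param outputDir artifact directory for [runPipeline()].
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1, outputDir = tempfile("coastpop-run-")) {
  list(
    seed = as.integer(seed),
    outputDir = outputDir,
    scene = list(nRows = 512L, nCols = 512L, cellSize = 100,
                 nProvinces = 4L, nCounties = 80L, townshipsPerCounty = 5L,
                 nSettlements = 25L, noiseSd = 0.3, totalPop = 2e6,
                 coastFraction = 0.3, ntlBloomingRadius = 1000),
    kde = list(bandwidth = 2000),
    model = list(nTrees = 500L, minLeaf = 4L),
    weightMode = "exp",
    lecz = list(elevThreshold = 10, distThreshold = 100000,
                connectivity = FALSE)
  )
}

#' Save / load a run configuration (YAML)
#'
#' \code{loadRunConfig(saveRunConfig(config, path))} reproduces the
#' configuration exactly.
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param path YAML file path.
#' @return \code{saveRunConfig}: \code{path}, invisibly;
#'   \code{loadRunConfig}: the configuration list.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  for (nm in names(base)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- base[[nm]]
    else if (is.list(base[[nm]]))
      for (sub in names(base[[nm]]))
        if (is.null(cfg[[nm]][[sub]])) cfg[[nm]][[sub]] <- base[[nm]][[sub]]
  }
  cfg
}

#' Run the full mapping pipeline
#'
#' Executes scene synthesis, covariate assembly, county-level model
#' fitting (both engines), dasymetric redistribution, LECZ extraction,
#' exposure accounting and township validation, writing every artifact
#' plus a manifest (configuration, per-file MD5 hashes, package version,
#' metrics) to \code{config$outputDir}. Identical configuration and seed
#' produce byte-identical rasters and an identical manifest. Any stage
#' failure aborts with the stage name and the underlying cause.
#'
#' @param config configuration list (see [defaultRunConfig()],
#'   [loadRunConfig()]).
#' @param quiet suppress stage progress messages.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), quiet = FALSE) {
  t0 <- Sys.time()
  outDir <- config$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[coastpop] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("synth: generating scene (seed ", config$seed, ")")
  scene <- stage("synth", {
    sc <- do.call(sceneConfig, c(config$scene, list(seed = config$seed)))
    generateScene(sc)
  })

  say("covariates: building six-layer stack")
  stack <- stage("covariates", suppressWarnings(
    buildCovariateStack(scene, bandwidth = config$kde$bandwidth)))

  say("fit: training table and both engines")
  tab <- stage("fit", buildTrainingTable(stack, scene@admin, "county"))
  rfFit <- stage("fit", fitRandomForest(tab, nTrees = config$model$nTrees,
                                        seed = deriveSeed(config$seed, 1)))
  m5Fit <- stage("fit", fitModelTree(tab, minLeaf = config$model$minLeaf))
  fits <- list(rf = rfFit, m5 = m5Fit)

  say("map: prediction, weights (mode ", config$weightMode,
      "), redistribution")
  pops <- stage("map", lapply(fits, function(f) {
    pred <- predictRaster(f, stack)
    W <- weightsFromPrediction(pred, config$weightMode)
    suppressWarnings(redistribute(W, scene@admin, "county"))
  }))

  say("lecz: mask and exposure")
  dist <- stage("lecz", distanceToCoast(scene@landMask))
  mask <- stage("lecz", extractLecz(scene@elevation, dist, scene@landMask,
                                    config$lecz$elevThreshold,
                                    config$lecz$distThreshold,
                                    config$lecz$connectivity))
  exposures <- stage("lecz", lapply(pops, function(p)
    exposureTable(p, mask, scene@admin, "province")))

  say("validate: township accuracy")
  metrics <- stage("validate", lapply(pops, function(p)
    evaluatePopulation(p, scene@admin, "township")))
  strat <- stage("validate", lapply(pops, function(p)
    stratifiedReport(p, scene@admin, "township")))

  say("writing artifacts to ", outDir)
  fp <- function(...) file.path(outDir, ...)
  writeAsciiGrid(scene@truePop, fp("true_pop.asc"))
  writeAsciiGrid(scene@admin@labels, fp("labels_township.asc"))
  for (nm in names(stack@layers))
    writeAsciiGrid(stack@layers[[nm]], fp(paste0("covariate_", nm, ".asc")))
  writeStackMetadata(stack, fp("stack_metadata.json"))
  utils::write.csv(scene@pois, fp("pois.csv"), row.names = FALSE)
  utils::write.csv(adminUnits(scene@admin), fp("units.csv"),
                   row.names = FALSE)
  utils::write.csv(tab, fp("training_table.csv"), row.names = FALSE)
  for (k in names(fits))
    utils::write.csv(fits[[k]]@importance,
                     fp(paste0("importance_", k, ".csv")), row.names = FALSE)
  for (k in names(pops))
    writeAsciiGrid(pops[[k]], fp(paste0("population_", k, ".asc")))
  writeAsciiGrid(mask, fp("lecz_mask.asc"))
  for (k in names(exposures))
    utils::write.csv(exposures[[k]], fp(paste0("exposure_", k, ".csv")),
                     row.names = FALSE)
  metricsOut <- list(
    township = metrics,
    stratified = lapply(strat, function(s) as.list(s)),
    oob_mse_rf = rfFit@oobMSE,
    pca_var_fraction = stack@metadata$pcaVarFraction
  )
  jsonlite::write_json(metricsOut, fp("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")

  files <- sort(list.files(outDir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(outDir, files)))
  names(hashes) <- files
  manifest <- list(
    package = "coastpop",
    version = as.character(utils::packageVersion("coastpop")),
    # outputDir is a location, not a parameter of the computation: leaving
    # it out keeps manifests of identical runs byte-identical
    config = config[setdiff(names(config), "outputDir")],
    metrics = metricsOut,
    files = hashes
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  say(sprintf("done in %.1f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(manifest)
}
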