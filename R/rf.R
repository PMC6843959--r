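#' @include AllClasses.R AllGenerics.R utils.R m5.R
NULL

#' Fit the bagged regression-forest engine
#'
#' Fits a bagged regression-tree ensemble (random forest) to the
#' county-level training table, keeping the in-bag matrix so that
#' out-of-bag (OOB) prediction error — the internal cross-validation that
#' replaces a set-aside test set — and OOB permutation importance can be
#' computed. Predictions are averages of training targets, so the
#' prediction raster can never leave the training target range.
#'
#' @param table training table from [buildTrainingTable()] (feature
#'   columns plus \code{y}); at least 10 rows.
#' @param nTrees number of trees (default 500).
#' @param mtry features tried per split (default \code{ceiling(p/3)}, the
#'   regression convention).
#' @param seed RNG seed; the fit is deterministic in it.
#' @param nRepeats permutation repeats for the stored importance table
#'   (see [permutationImportance()]).
#' @return a [FittedModel-class] with \code{kind = "rf"} and the OOB MSE
#'   in \code{@oobMSE}.
#' @export
fitRandomForest <- function(table, nTrees = 500,
                            mtry = NULL, seed = 1, nRepeats = 10) {
  d <- checkTrainingTable(table)
  X <- d$X; y <- d$y
  if (nrow(X) < 10)
    stop("need at least 10 training rows for the forest", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0))
    stop("all features are constant; nothing to learn from", call. = FALSE)
  if (is.null(mtry)) mtry <- ceiling(ncol(X) / 3)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(X, y, ntree = nTrees, mtry = mtry,
                                   keep.inbag = TRUE)
  model <- new("FittedModel", kind = "rf", fit = rf,
               features = colnames(X), yRange = range(y),
               oobMSE = as.numeric(rf$mse[length(rf$mse)]),
               importance = data.frame(), rules = list())
  model@importance <- permutationImportance(model, table,
                                            nRepeats = nRepeats,
                                            seed = deriveSeed(seed, 101))
  model
}

# OOB predictions of a kept-inbag forest, optionally with one feature column
# replaced; rows with no OOB tree (rare) fall back to the full-forest mean
oobPredictions <- function(rf, X) {
  ind <- stats::predict(rf, X, predict.all = TRUE)$individual
  oob <- rf$inbag == 0
  s <- rowSums(ind * oob)
  n <- rowSums(oob)
  out <- ifelse(n > 0, s / pmax(n, 1), rowMeans(ind))
  out
}

#' Permutation importance (\%IncMSE) of a fitted forest
#'
#' For each feature, the mean percent increase of the out-of-bag MSE over
#' \code{nRepeats} independent permutations of that feature's column:
#' permuting an informative feature breaks its relation to the target and
#' inflates the OOB error, while permuting pure noise changes nothing.
#'
#' @param model a [FittedModel-class] of kind \code{"rf"} fitted with
#'   [fitRandomForest()].
#' @param table the training table the model was fitted on.
#' @param nRepeats number of independent permutations per feature
#'   (>= 1).
#' @param seed RNG seed; the scores are deterministic in it.
#' @return \code{data.frame(feature, inc_mse_pct)}.
#' @export
permutationImportance <- function(model, table, nRepeats = 10, seed = 1) {
  if (!is(model, "FittedModel") || model@kind != "rf")
    stop("permutation importance requires a fitted forest model",
         call. = FALSE)
  if (nRepeats < 1) stop("nRepeats must be >= 1", call. = FALSE)
  d <- checkTrainingTable(table)
  X <- d$X; y <- d$y
  if (!identical(colnames(X), model@features))
    stop("table features do not match the fitted model", call. = FALSE)
  rf <- model@fit
  base <- mean((oobPredictions(rf, X) - y)^2)
  set.seed(as.integer(seed))
  inc <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    mses <- numeric(nRepeats)
    for (r in seq_len(nRepeats)) {
      Xp <- X
      Xp[, j] <- X[sample(nrow(X)), j]
      mses[r] <- mean((oobPredictions(rf, Xp) - y)^2)
    }
    inc[j] <- 100 * (mean(mses) - base) / base
  }
  data.frame(feature = model@features, inc_mse_pct = inc, row.names = NULL)
}

#' Predict from a fitted log-density model
#'
#' @param object a [FittedModel-class].
#' @param newdata matrix or data.frame containing the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric vector of predicted ln densities.
#' @export
setMethod("predict", "FittedModel", function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object@features, drop = FALSE])
  storage.mode(X) <- "double"
  if (object@kind == "rf") {
    as.numeric(stats::predict(object@fit, X))
  } else {
    m5PredictMatrix(object@fit$tree, X, smooth = object@fit$smooth,
                    k = object@fit$k)
  }
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel (%s): %d features, training y range [%.3f, %.3f]\n",
              object@kind, length(object@features),
              object@yRange[1], object@yRange[2]))
  if (object@kind == "rf")
    cat(sprintf("  OOB MSE: %.4f\n", object@oobMSE))
  else
    cat(sprintf("  %d rules\n", length(object@rules)))
})

#' Apply a fitted model to a covariate stack, cell by cell
#'
#' Predicts ln density for every cell whose six features are all valid;
#' any nodata feature makes the output cell nodata. The result equals a
#' scalar [predict()] call on each cell's feature vector.
#'
#' @param model a [FittedModel-class].
#' @param stack an aligned [CovariateStack-class] whose layer names match
#'   the model's features.
#' @return [GeoRaster-class] of predicted ln density.
#' @export
predictRaster <- function(model, stack) {
  stopifnot(is(model, "FittedModel"), is(stack, "CovariateStack"))
  if (!all(model@features %in% names(stack@layers)))
    stop("stack layers do not provide the model's features: ",
         paste(setdiff(model@features, names(stack@layers)), collapse = ", "),
         call. = FALSE)
  M <- vapply(model@features, function(nm) as.vector(stack@layers[[nm]]@values),
              numeric(stack@spec@nRows * stack@spec@nCols))
  valid <- rowSums(is.na(M)) == 0
  out <- rep(NA_real_, nrow(M))
  if (any(valid)) {
    colnames(M) <- model@features
    out[valid] <- predict(model, M[valid, , drop = FALSE])
  }
  geoRaster(matrix(out, stack@spec@nRows, stack@spec@nCols), stack@spec)
}
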