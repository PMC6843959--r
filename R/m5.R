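#' @include AllClasses.R AllGenerics.R utils.R
NULL

# ---- M5'-style rule-based model tree -------------------------------------
#
# Greedy growth on the standard-deviation-reduction (SDR) criterion
#   SDR = sd(S) - sum_i (|S_i|/|S|) sd(S_i),
# least-squares linear models at every node restricted to the features
# used by splits in the node's subtree (terminal leaves: the node mean),
# greedy backward term elimination and subtree replacement ("pruning")
# under the penalized error estimate err * (n + v)/(n - v) with v = number
# of model parameters, and optional leaf-to-root smoothing with the
# classic k = 15. Split ties are broken by lowest feature index, then
# lowest threshold, so refits are reproducible.

m5SplitSearch <- function(X, y, minLeaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- X[, j]
    o <- order(xs)
    xo <- xs[o]; yo <- y[o]
    # candidate thresholds: midpoints between consecutive distinct values
    cum <- cumsum(yo); cum2 <- cumsum(yo^2)
    tot <- cum[n]; tot2 <- cum2[n]
    sdAll <- sdFromSums(tot, tot2, n)
    iCand <- which(diff(xo) > 0)            # split after position i
    iCand <- iCand[iCand >= minLeaf & (n - iCand) >= minLeaf]
    if (!length(iCand)) next
    nl <- iCand; nr <- n - iCand
    sdl <- sdFromSums(cum[iCand], cum2[iCand], nl)
    sdr_ <- sdFromSums(tot - cum[iCand], tot2 - cum2[iCand], nr)
    gain <- sdAll - (nl / n) * sdl - (nr / n) * sdr_
    k <- which.max(gain)
    thr <- (xo[iCand[k]] + xo[iCand[k] + 1]) / 2
    cand <- list(feature = j, threshold = thr, gain = gain[k])
    if (is.null(best) ||
        cand$gain > best$gain + 1e-12 ||
        (abs(cand$gain - best$gain) <= 1e-12 &&
         (cand$feature < best$feature ||
          (cand$feature == best$feature && cand$threshold < best$threshold))))
      best <- cand
  }
  best
}

sdFromSums <- function(s, s2, n) {
  v <- (s2 - s^2 / n) / pmax(n - 1, 1)
  sqrt(pmax(v, 0))
}

m5Grow <- function(X, y, rows, minLeaf, sdRoot) {
  n <- length(rows)
  sdHere <- if (n > 1) stats::sd(y[rows]) else 0
  leaf <- list(type = "leaf", rows = rows, n = n)
  if (n < 2 * minLeaf || sdHere < 0.05 * sdRoot) return(leaf)
  sp <- m5SplitSearch(X[rows, , drop = FALSE], y[rows], minLeaf)
  if (is.null(sp) || sp$gain <= 1e-12) return(leaf)
  goLeft <- X[rows, sp$feature] <= sp$threshold
  list(type = "node", rows = rows, n = n,
       feature = sp$feature, threshold = sp$threshold,
       left = m5Grow(X, y, rows[goLeft], minLeaf, sdRoot),
       right = m5Grow(X, y, rows[!goLeft], minLeaf, sdRoot))
}

subtreeFeatures <- function(node) {
  if (node$type == "leaf") return(integer())
  sort(unique(c(node$feature,
                subtreeFeatures(node$left), subtreeFeatures(node$right))))
}

# least-squares fit of y ~ X[, feats] with greedy backward elimination
# under the adjusted error; returns coefficients (intercept + named terms)
m5FitModel <- function(X, y, rows, feats) {
  n <- length(rows)
  fitErr <- function(fs) {
    if (!length(fs)) {
      mu <- mean(y[rows])
      res <- y[rows] - mu
      return(list(coef = c(`(Intercept)` = mu), feats = integer(),
                  mae = mean(abs(res))))
    }
    Xs <- cbind(1, X[rows, fs, drop = FALSE])
    fit <- stats::lm.fit(Xs, y[rows])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    res <- y[rows] - Xs %*% cf
    names(cf) <- c("(Intercept)", colnames(X)[fs])
    list(coef = cf, feats = fs, mae = mean(abs(res)))
  }
  adj <- function(m) {
    v <- length(m$feats) + 1
    if (n <= v) return(Inf)
    m$mae * (n + v) / (n - v)
  }
  cur <- fitErr(feats)
  repeat {
    if (!length(cur$feats)) break
    trials <- lapply(seq_along(cur$feats),
                     function(i) fitErr(cur$feats[-i]))
    errs <- vapply(trials, adj, numeric(1))
    if (min(errs) < adj(cur)) cur <- trials[[which.min(errs)]]
    else break
  }
  cur
}

m5AttachModels <- function(node, X, y) {
  feats <- subtreeFeatures(node)
  node$model <- m5FitModel(X, y, node$rows, feats)
  if (node$type == "node") {
    node$left <- m5AttachModels(node$left, X, y)
    node$right <- m5AttachModels(node$right, X, y)
  }
  node
}

m5PredictNode <- function(node, x) {
  cf <- node$model$coef
  p <- cf[1]
  fs <- node$model$feats
  if (length(fs)) p <- p + sum(cf[-1] * x[fs])
  unname(p)
}

# raw (unsmoothed) subtree predictions for the node's training rows
m5SubtreePred <- function(node, X) {
  if (node$type == "leaf")
    return(vapply(node$rows, function(r) m5PredictNode(node, X[r, ]),
                  numeric(1)))
  goLeft <- X[node$rows, node$feature] <= node$threshold
  out <- numeric(node$n)
  out[goLeft] <- m5SubtreePred(node$left, X)
  out[!goLeft] <- m5SubtreePred(node$right, X)
  out
}

m5Prune <- function(node, X, y) {
  if (node$type == "leaf") return(node)
  node$left <- m5Prune(node$left, X, y)
  node$right <- m5Prune(node$right, X, y)
  n <- node$n
  v <- length(node$model$feats) + 1
  nodeAdj <- if (n > v) node$model$mae * (n + v) / (n - v) else Inf
  sub <- m5SubtreePred(node, X)
  subMae <- mean(abs(y[node$rows] - sub))
  # penalize the subtree by its own parameter count (all leaf model terms)
  vSub <- m5CountParams(node)
  subAdj <- if (n > vSub) subMae * (n + vSub) / (n - vSub) else Inf
  if (nodeAdj <= subAdj) {
    node <- list(type = "leaf", rows = node$rows, n = n, model = node$model)
  }
  node
}

m5CountParams <- function(node) {
  if (node$type == "leaf") return(length(node$model$feats) + 1)
  m5CountParams(node$left) + m5CountParams(node$right)
}

m5PredictOne <- function(node, x, smooth, k = 15) {
  if (node$type == "leaf") return(m5PredictNode(node, x))
  child <- if (x[node$feature] <= node$threshold) node$left else node$right
  p <- m5PredictOne(child, x, smooth, k)
  if (smooth) (child$n * p + k * m5PredictNode(node, x)) / (child$n + k)
  else p
}

# vectorized prediction for a matrix of query rows; identical to applying
# m5PredictOne to each row
m5PredictNodeMat <- function(node, X, idx) {
  cf <- node$model$coef
  fs <- node$model$feats
  p <- rep.int(cf[1], length(idx))
  if (length(fs)) p <- p + as.vector(X[idx, fs, drop = FALSE] %*% cf[-1])
  p
}

m5PredictMatrix <- function(node, X, idx = seq_len(nrow(X)), smooth = TRUE,
                            k = 15) {
  if (!length(idx)) return(numeric())
  if (node$type == "leaf") return(m5PredictNodeMat(node, X, idx))
  goLeft <- X[idx, node$feature] <= node$threshold
  out <- numeric(length(idx))
  out[goLeft] <- m5PredictMatrix(node$left, X, idx[goLeft], smooth, k)
  out[!goLeft] <- m5PredictMatrix(node$right, X, idx[!goLeft], smooth, k)
  if (smooth) {
    np <- m5PredictNodeMat(node, X, idx)
    nl <- node$left$n; nr <- node$right$n
    out[goLeft] <- (nl * out[goLeft] + k * np[goLeft]) / (nl + k)
    out[!goLeft] <- (nr * out[!goLeft] + k * np[!goLeft]) / (nr + k)
  }
  out
}

m5Rules <- function(node, featNames, conds = list()) {
  if (node$type == "leaf") {
    return(list(list(
      conditions = conds,
      n = node$n,
      coefficients = node$model$coef
    )))
  }
  fn <- featNames[node$feature]
  c(m5Rules(node$left, featNames,
            c(conds, list(list(feature = fn, op = "<=",
                               value = node$threshold)))),
    m5Rules(node$right, featNames,
            c(conds, list(list(feature = fn, op = ">",
                               value = node$threshold)))))
}

m5VarImp <- function(tree, featNames, nAll) {
  condRows <- stats::setNames(numeric(length(featNames)), featNames)
  modelRows <- condRows
  walk <- function(node, pathFeats) {
    if (node$type == "leaf") {
      for (f in unique(pathFeats))
        condRows[f] <<- condRows[f] + node$n
      used <- featNames[node$model$feats]
      nz <- used[abs(node$model$coef[-1]) > 0]
      for (f in unique(nz))
        modelRows[f] <<- modelRows[f] + node$n
      return(invisible())
    }
    walk(node$left, c(pathFeats, featNames[node$feature]))
    walk(node$right, c(pathFeats, featNames[node$feature]))
  }
  walk(tree, character())
  data.frame(feature = featNames,
             varimp_pct = (100 * condRows / nAll + 100 * modelRows / nAll) / 2,
             cond_pct = 100 * condRows / nAll,
             model_pct = 100 * modelRows / nAll,
             row.names = NULL)
}

#' Fit an M5-style rule-based model tree
#'
#' Fits a model tree to county-level training data: greedy binary splits
#' chosen by standard-deviation reduction, least-squares linear models in
#' the (pruned) leaves restricted to features used in each leaf's former
#' subtree, penalized-error pruning and optional leaf-to-root smoothing.
#' The fitted tree is exported as a rule list (conjunctions of split
#' conditions, each with its leaf model) and carries the usage-based
#' VarImp(\%) importance: per feature, the mean of the percentage of
#' training rows whose rule conditions test the feature and the percentage
#' whose leaf model uses it.
#'
#' Unlike the bagged forest, the leaf linear models extrapolate: raster
#' predictions may exceed the training target range.
#'
#' @param table training table from [buildTrainingTable()] (feature
#'   columns plus \code{y}).
#' @param minLeaf minimum rows per side of a split (default 4).
#' @param prune apply penalized-error subtree replacement (default TRUE).
#' @param smooth apply leaf-to-root smoothing with k = 15 (default TRUE).
#' @return a [FittedModel-class] with \code{kind = "m5"}.
#' @export
fitModelTree <- function(table, minLeaf = 4, prune = TRUE, smooth = TRUE) {
  d <- checkTrainingTable(table)
  X <- d$X; y <- d$y
  sdRoot <- if (length(y) > 1) stats::sd(y) else 0
  if (sdRoot == 0) {
    # degenerate constant-target input: a single constant rule
    tree <- list(type = "leaf", rows = seq_along(y), n = length(y),
                 model = list(coef = c(`(Intercept)` = y[1]),
                              feats = integer(), mae = 0))
  } else {
    tree <- m5Grow(X, y, seq_along(y), minLeaf, sdRoot)
    if (tree$type == "leaf") {
      # unsplittable root (minLeaf >= n): one global linear model
      tree$model <- m5FitModel(X, y, tree$rows, seq_len(ncol(X)))
    } else {
      tree <- m5AttachModels(tree, X, y)
      if (prune) tree <- m5Prune(tree, X, y)
    }
  }
  featNames <- colnames(X)
  fit <- list(tree = tree, smooth = smooth, k = 15, featNames = featNames)
  new("FittedModel", kind = "m5", fit = fit, features = featNames,
      yRange = range(y), oobMSE = NA_real_,
      importance = m5VarImp(tree, featNames, length(y)),
      rules = m5Rules(tree, featNames))
}

# shared feature/target extraction and checks for both engines
checkTrainingTable <- function(table) {
  feats <- intersect(covariateNames(), colnames(table))
  if (!length(feats))
    feats <- setdiff(colnames(table), c("unit_id", "y"))
  if (!"y" %in% colnames(table))
    stop("training table must have a 'y' column (ln density)", call. = FALSE)
  X <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(table$y)
  if (anyNA(X) || anyNA(y))
    stop("training table contains missing values; drop such units first",
         call. = FALSE)
  if (!all(is.finite(y)))
    stop("training target must be finite (zero-population units must be dropped)",
         call. = FALSE)
  list(X = X, y = y)
}
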