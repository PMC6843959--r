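# the two regression engines: bagged forest with OOB machinery and the
# M5-style rule model tree

test_that("forest on a constant target predicts the constant with zero OOB error", {
  set.seed(20)
  tab <- data.frame(matrix(rnorm(120), 20, 6))
  colnames(tab) <- c(paste0("f", 1:5), "noise_feat")
  tab$y <- 5
  rf <- suppressWarnings(fitRandomForest(tab, nTrees = 100, seed = 1,
                                         nRepeats = 1))
  expect_equal(unique(predict(rf, tab)), 5)
  expect_equal(rf@oobMSE, 0)
})

test_that("forest recovers a noiseless linear signal with high OOB R2", {
  tab <- syntheticTable(n = 200, seed = 21, noise = 0)
  rf <- fitRandomForest(tab, nTrees = 300, mtry = 4, seed = 2, nRepeats = 1)
  r2 <- 1 - rf@oobMSE / stats::var(tab$y)
  expect_gt(r2, 0.9)
})

test_that("forest predictions never leave the training target range", {
  tab <- syntheticTable(n = 100, seed = 22)
  rf <- fitRandomForest(tab, nTrees = 200, seed = 3, nRepeats = 1)
  extreme <- tab[1:10, ]
  extreme[, 1:6] <- extreme[, 1:6] * 100  # far outside the training cloud
  p <- predict(rf, extreme)
  expect_true(all(p >= rf@yRange[1] & p <= rf@yRange[2]))
})

test_that("forest fitting is deterministic in the seed and guards its preconditions", {
  tab <- syntheticTable(n = 60, seed = 23)
  a <- fitRandomForest(tab, nTrees = 100, seed = 9, nRepeats = 2)
  b <- fitRandomForest(tab, nTrees = 100, seed = 9, nRepeats = 2)
  expect_identical(predict(a, tab), predict(b, tab))
  expect_identical(a@importance, b@importance)
  expect_error(fitRandomForest(tab[1:5, ]), "at least 10")
  const <- tab; const[, 1:6] <- 1
  expect_error(fitRandomForest(const), "constant")
})

test_that("permutation importance zeroes out pure noise and finds the dominant signal", {
  tab <- syntheticTable(n = 150, seed = 24)
  rf <- fitRandomForest(tab, nTrees = 300, seed = 4, nRepeats = 5)
  imp <- rf@importance
  dom <- imp$inc_mse_pct[imp$feature == "f1"]
  noise <- imp$inc_mse_pct[imp$feature == "noise_feat"]
  expect_gt(dom, 10)
  expect_lt(abs(noise), dom / 10)
  expect_error(permutationImportance(rf, tab, nRepeats = 0), "nRepeats")
  m5 <- fitModelTree(tab)
  expect_error(permutationImportance(m5, tab), "forest")
})

test_that("model tree collapses globally linear noiseless data to one rule matching OLS", {
  set.seed(25)
  x1 <- rnorm(100); x2 <- rnorm(100)
  tab <- data.frame(x1 = x1, x2 = x2, y = 2 * x1 - x2)
  m5 <- fitModelTree(tab)
  expect_length(m5@rules, 1)
  ols <- stats::lm(y ~ x1 + x2, tab)
  expect_equal(predict(m5, tab), unname(stats::predict(ols, tab)),
               tolerance = 1e-6)
})

test_that("model tree finds the step boundary located by exhaustive SDR search", {
  set.seed(26)
  x <- c(runif(10, -1, -0.05), runif(10, 0.05, 1))
  tab <- data.frame(x = x, z = rnorm(20), y = ifelse(x < 0, 0, 10))
  m5 <- fitModelTree(tab, minLeaf = 2, prune = FALSE, smooth = FALSE)
  X <- as.matrix(tab[, c("x", "z")])
  oracle <- oracleM5Tree(X, tab$y, 1:20, 2, stats::sd(tab$y))
  expect_false(oracle$leaf)
  root <- m5@fit$tree
  expect_equal(root$feature, oracle$feature)
  expect_equal(root$threshold, oracle$threshold)
  # the boundary separates the two plateaus
  expect_true(root$threshold > max(x[x < 0]) - 1e-12 &&
              root$threshold < min(x[x > 0]) + 1e-12)
})

test_that("unsplittable input yields a single global linear leaf; constant target a constant rule", {
  tab <- syntheticTable(n = 12, seed = 27, noise = 0)
  m5 <- fitModelTree(tab, minLeaf = 12)
  expect_length(m5@rules, 1)
  expect_length(m5@rules[[1]]$conditions, 0)
  # global least-squares model reproduces the linear signal
  expect_equal(predict(m5, tab), tab$y, tolerance = 1e-8)
  const <- tab; const$y <- 3.5
  mc <- fitModelTree(const)
  expect_length(mc@rules, 1)
  expect_equal(unique(predict(mc, const)), 3.5)
})

test_that("unpruned tree structure equals the exhaustive greedy-SDR oracle on small tables", {
  for (seed in 1:5) {
    set.seed(seed + 300)
    n <- sample(8:12, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    colnames(X) <- paste0("v", 1:3)
    y <- X[, 1] + 0.5 * X[, 2]^2 + rnorm(n, 0, 0.2)
    tab <- cbind(as.data.frame(X), y = y)
    m5 <- fitModelTree(tab, minLeaf = 1, prune = FALSE, smooth = FALSE)
    oracle <- oracleM5Tree(X, y, seq_len(n), 1, stats::sd(y))
    expect_identical(treeShape(m5@fit$tree), oracle)
  }
})

test_that("model-tree VarImp covers all features, lies in [0, 100] and tracks usage", {
  tab <- syntheticTable(n = 120, seed = 28)
  m5 <- fitModelTree(tab)
  imp <- m5@importance
  expect_setequal(imp$feature, colnames(tab)[1:6])
  expect_true(all(imp$varimp_pct >= 0 & imp$varimp_pct <= 100))
  expect_equal(imp$varimp_pct, (imp$cond_pct + imp$model_pct) / 2)
})

test_that("model tree fitting is deterministic given the input ordering", {
  tab <- syntheticTable(n = 80, seed = 29)
  a <- fitModelTree(tab)
  b <- fitModelTree(tab)
  expect_identical(a@rules, b@rules)
  expect_identical(predict(a, tab), predict(b, tab))
})

test_that("raster prediction equals scalar predictions cell by cell and propagates nodata", {
  sc <- tinyScene(seed = 6, nRows = 32, nCols = 32, nCounties = 10)
  stack <- quietStack(sc)
  tab <- suppressMessages(buildTrainingTable(stack, sc@admin, "county"))
  rf <- fitRandomForest(tab, nTrees = 100, seed = 5, nRepeats = 1)
  pr <- predictRaster(rf, stack)
  v <- rasterValues(pr)
  M <- sapply(stackLayers(stack), function(r) as.vector(rasterValues(r)))
  valid <- which(rowSums(is.na(M)) == 0)
  set.seed(30)
  for (i in sample(valid, 10)) {
    q <- as.data.frame(as.list(M[i, ]))
    expect_identical(v[i], predict(rf, q))
  }
  # nodata features (sea cells) stay nodata in the prediction
  expect_true(all(is.na(v[rasterValues(sc@landMask) == 0])))
  # constant model -> constant raster on valid cells
  const <- tab; const$y <- 2
  cm <- fitModelTree(const)
  cv <- rasterValues(predictRaster(cm, stack))
  expect_equal(unique(cv[!is.na(cv)]), 2)
})
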