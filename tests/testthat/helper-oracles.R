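# Independent brute-force oracles and small scene factories shared across
# the suite. Every oracle recomputes the quantity by direct enumeration,
# never by calling the implementation path it checks.

# small, fast scene for pipeline-level tests
tinyScene <- function(seed = 1, nRows = 64, nCols = 64, nCounties = 12,
                      townshipsPerCounty = 3, ...) {
  generateScene(sceneConfig(nRows = nRows, nCols = nCols,
                            nCounties = nCounties,
                            townshipsPerCounty = townshipsPerCounty,
                            nSettlements = 8, seed = seed, ...))
}

quietStack <- function(scene, ...) {
  suppressWarnings(suppressMessages(buildCovariateStack(scene, ...)))
}

quietRedistribute <- function(W, admin, level = "county") {
  suppressWarnings(redistribute(W, admin, level))
}

# per-cell dictionary-accumulation zonal statistics
oracleZonal <- function(values, labels, stat) {
  acc <- list()
  cnt <- list()
  for (i in seq_along(values)) {
    l <- labels[i]
    if (is.na(l) || l == 0) next
    key <- as.character(l)
    if (is.null(acc[[key]])) { acc[[key]] <- 0; cnt[[key]] <- 0 }
    if (!is.na(values[i])) {
      acc[[key]] <- acc[[key]] + values[i]
      cnt[[key]] <- cnt[[key]] + 1
    }
  }
  ids <- sort(as.numeric(names(acc)))
  out <- vapply(as.character(ids), function(k) {
    if (cnt[[k]] == 0) return(NA_real_)
    switch(stat, sum = acc[[k]], count = cnt[[k]], mean = acc[[k]] / cnt[[k]])
  }, numeric(1))
  data.frame(unit_id = ids, value = unname(out))
}

# exhaustive all-pairs distance to the nearest sea cell (centre to centre)
oracleDistance <- function(land, cellSize) {
  sea <- which(land == 0, arr.ind = TRUE)
  out <- matrix(0, nrow(land), ncol(land))
  for (r in seq_len(nrow(land))) for (c in seq_len(ncol(land))) {
    if (land[r, c] == 0) next
    out[r, c] <- sqrt(min((sea[, 1] - r)^2 + (sea[, 2] - c)^2)) * cellSize
  }
  out
}

# per-cell explicit-loop recomputation of the Horn 3x3 gradient
oracleSlopeHorn <- function(z, cellSize) {
  nr <- nrow(z); nc <- ncol(z)
  cl <- function(i, n) min(max(i, 1), n)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    nb <- matrix(NA_real_, 3, 3)
    for (dr in -1:1) for (dc in -1:1)
      nb[dr + 2, dc + 2] <- z[cl(r + dr, nr), cl(c + dc, nc)]
    if (anyNA(nb)) next
    dzdx <- ((nb[1, 3] + 2 * nb[2, 3] + nb[3, 3]) -
             (nb[1, 1] + 2 * nb[2, 1] + nb[3, 1])) / (8 * cellSize)
    dzdy <- ((nb[3, 1] + 2 * nb[3, 2] + nb[3, 3]) -
             (nb[1, 1] + 2 * nb[1, 2] + nb[1, 3])) / (8 * cellSize)
    out[r, c] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  }
  out
}

# brute-force nearest-source-centre resampling
oracleNearest <- function(srcVals, srcSpec, target) {
  out <- matrix(NA_real_, target@nRows, target@nCols)
  for (r in seq_len(target@nRows)) for (c in seq_len(target@nCols)) {
    x <- target@originX + (c - 0.5) * target@cellSize
    y <- target@originY - (r - 0.5) * target@cellSize
    bestD <- Inf; bestV <- NA_real_
    for (sr in seq_len(srcSpec@nRows)) for (sc_ in seq_len(srcSpec@nCols)) {
      sx <- srcSpec@originX + (sc_ - 0.5) * srcSpec@cellSize
      sy <- srcSpec@originY - (sr - 0.5) * srcSpec@cellSize
      d <- (x - sx)^2 + (y - sy)^2
      if (d < bestD) { bestD <- d; bestV <- srcVals[sr, sc_] }
    }
    # respect the extent rule: outside the source extent stays nodata
    inX <- x >= srcSpec@originX &
      x <= srcSpec@originX + srcSpec@nCols * srcSpec@cellSize
    inY <- y <= srcSpec@originY &
      y >= srcSpec@originY - srcSpec@nRows * srcSpec@cellSize
    if (inX && inY) out[r, c] <- bestV
  }
  out
}

# per-point quartic-kernel summation at each cell centre
oracleKde <- function(px, py, spec, h) {
  out <- matrix(0, spec@nRows, spec@nCols)
  for (r in seq_len(spec@nRows)) for (c in seq_len(spec@nCols)) {
    x <- spec@originX + (c - 0.5) * spec@cellSize
    y <- spec@originY - (r - 0.5) * spec@cellSize
    s <- 0
    for (i in seq_along(px)) {
      d2 <- (x - px[i])^2 + (y - py[i])^2
      if (d2 < h^2) s <- s + 3 / (pi * h^2) * (1 - d2 / h^2)^2
    }
    out[r, c] <- s
  }
  out
}

# per-cell double-loop LECZ membership
oracleLecz <- function(elev, dist, land, eThr, dThr) {
  out <- matrix(0, nrow(elev), ncol(elev))
  for (r in seq_len(nrow(elev))) for (c in seq_len(ncol(elev))) {
    e <- elev[r, c]
    if (land[r, c] == 1 && !is.na(e) && e < eThr && dist[r, c] < dThr)
      out[r, c] <- 1
  }
  out
}

# independent greedy SDR tree (structure only), sharing the published
# stopping rules: n < 2*minLeaf, sd < 5% of root sd, or no positive gain
oracleM5Tree <- function(X, y, rows, minLeaf, sdRoot) {
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  n <- length(rows)
  sdHere <- sd0(y[rows])
  if (n < 2 * minLeaf || sdHere < 0.05 * sdRoot) return(list(leaf = TRUE))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[rows, j]))
    if (length(xs) < 2) next
    for (t in (xs[-length(xs)] + xs[-1]) / 2) {
      left <- X[rows, j] <= t
      nl <- sum(left); nr <- n - nl
      if (nl < minLeaf || nr < minLeaf) next
      sdr <- sdHere - (nl / n) * sd0(y[rows][left]) -
        (nr / n) * sd0(y[rows][!left])
      if (is.null(best) || sdr > best$gain + 1e-12) {
        best <- list(feature = j, threshold = t, gain = sdr)
      }
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(list(leaf = TRUE))
  left <- X[rows, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = oracleM5Tree(X, y, rows[left], minLeaf, sdRoot),
       right = oracleM5Tree(X, y, rows[!left], minLeaf, sdRoot))
}

# strip an implementation tree down to comparable structure
treeShape <- function(node) {
  if (node$type == "leaf") return(list(leaf = TRUE))
  list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
       left = treeShape(node$left), right = treeShape(node$right))
}

# synthetic regression table: 5 informative features + 1 pure-noise column
syntheticTable <- function(n = 150, seed = 1, betas = c(3, 1, 0.5, 0.3, 0.2),
                           noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- c(paste0("f", 1:5), "noise_feat")
  y <- X[, 1:5] %*% betas + rnorm(n, 0, noise)
  cbind(as.data.frame(X), y = as.numeric(y))
}
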