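# internal helpers shared across modules

#' @include AllClasses.R
NULL

# fixed covariate order; model feature names are stable across runs
covariateNames <- function() {
  c("ntl", "ndvi_max", "elevation", "slope", "guf", "poi_den")
}

# grid equality: same shape, geometry (to a metre-scale tolerance) and CRS tag
sameGrid <- function(a, b, tol = 1e-6) {
  a@nRows == b@nRows && a@nCols == b@nCols &&
    abs(a@originX - b@originX) < tol &&
    abs(a@originY - b@originY) < tol &&
    abs(a@cellSize - b@cellSize) < tol &&
    identical(a@crsTag, b@crsTag)
}

stopIfMisaligned <- function(a, b, what = "rasters") {
  if (!sameGrid(a, b))
    stop(what, " are not on the same grid (shape, origin, cell size and ",
         "CRS tag must match)", call. = FALSE)
  invisible(TRUE)
}

# map coordinates of all cell centres, in matrix layout
cellCenterX <- function(spec) {
  matrix(spec@originX + (seq_len(spec@nCols) - 0.5) * spec@cellSize,
         spec@nRows, spec@nCols, byrow = TRUE)
}
cellCenterY <- function(spec) {
  matrix(spec@originY - (seq_len(spec@nRows) - 0.5) * spec@cellSize,
         spec@nRows, spec@nCols)
}

# separable Gaussian blur with edge replication; sigma in cells
gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-h:h, sd = sigma)
  w <- w / sum(w)
  pass <- function(x) { # along rows (down columns)
    nr <- nrow(x)
    out <- matrix(0, nr, ncol(x))
    for (o in -h:h) {
      idx <- pmin(pmax(seq_len(nr) + o, 1L), nr)
      out <- out + w[o + h + 1L] * x[idx, , drop = FALSE]
    }
    out
  }
  t(pass(t(pass(m))))
}

# deterministic seed derivation, kept below 2^31
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
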