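#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Create a grid geometry
#'
#' @param nRows,nCols grid dimensions.
#' @param originX,originY map coordinates (m) of the north-west corner.
#' @param cellSize cell edge length in metres (default 100, the target
#'   mapping resolution).
#' @param crsTag opaque CRS label; rasters only interoperate when their
#'   tags are equal.
#' @return a [GridSpec-class].
#' @examples
#' GridSpec(2, 3)
#' @export
GridSpec <- function(nRows, nCols, originX = 0, originY = nRows * cellSize,
                     cellSize = 100, crsTag = "local-metric") {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      originX = as.numeric(originX), originY = as.numeric(originY),
      cellSize = as.numeric(cellSize), crsTag = as.character(crsTag))
}

#' Create a raster from a matrix
#'
#' @param values numeric matrix (\code{NA} = nodata); row 1 is the
#'   northernmost row.
#' @param spec a [GridSpec-class]; defaults to a grid matching the matrix
#'   with 100 m cells at origin (0, nRows * 100).
#' @param nodata sentinel written for \code{NA} cells on file output.
#' @return a [GeoRaster-class].
#' @examples
#' geoRaster(matrix(1:6, 2, 3))
#' @export
geoRaster <- function(values, spec = NULL, nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(spec)) spec <- GridSpec(nrow(values), ncol(values))
  new("GeoRaster", spec = spec, values = values, nodata = as.numeric(nodata))
}

#' @describeIn rasterValues value matrix of a GeoRaster
#' @export
setMethod("rasterValues", "GeoRaster", function(x) x@values)

#' @describeIn gridSpec geometry of a GeoRaster
#' @export
setMethod("gridSpec", "GeoRaster", function(x) x@spec)

#' @describeIn gridSpec shared geometry of a CovariateStack
#' @export
setMethod("gridSpec", "CovariateStack", function(x) x@spec)

#' @describeIn gridSpec geometry of a Scene
#' @export
setMethod("gridSpec", "Scene", function(x) x@config@spec)

#' @describeIn nodataMask nodata mask of a GeoRaster
#' @export
setMethod("nodataMask", "GeoRaster", function(x) is.na(x@values))

#' @describeIn stackLayers layers of a CovariateStack
#' @export
setMethod("stackLayers", "CovariateStack", function(x) x@layers)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g), crs '%s'\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY, object@crsTag))
})

setMethod("show", "GeoRaster", function(object) {
  v <- object@values
  ok <- !is.na(v)
  rng <- if (any(ok)) sprintf("[%g, %g]", min(v[ok]), max(v[ok])) else "[all nodata]"
  cat(sprintf("GeoRaster: %d x %d cells of %g m; values %s; %d nodata cells\n",
              object@spec@nRows, object@spec@nCols, object@spec@cellSize,
              rng, sum(!ok)))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack: %d layers (%s) on %d x %d grid\n",
              length(object@layers), paste(names(object@layers), collapse = ", "),
              object@spec@nRows, object@spec@nCols))
  vf <- object@metadata$pcaVarFraction
  if (!is.null(vf) && is.finite(vf))
    cat(sprintf("  POI composite: quartic KDE bandwidth %g m, PC1 variance fraction %.3f\n",
                object@metadata$bandwidth, vf))
})

# ---- file I/O: ESRI ASCII grid (+ .prj sidecar for the CRS tag) ----------

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads a single-band plain-text raster (\code{.asc}). The optional
#' \code{.prj} sidecar written by [writeAsciiGrid()] restores the CRS tag.
#' Cells equal to the file's \code{NODATA_value} become \code{NA};
#' [nodataMask()] reports exactly those cells.
#'
#' @param path path to the \code{.asc} file.
#' @return a [GeoRaster-class].
#' @seealso [writeAsciiGrid()]
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path))
    stop("raster file not found: ", path, call. = FALSE)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated header in ", path, call. = FALSE)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("missing header field '", k, "' in ", path,
                                call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cells, found ", length(vals), " in ", path,
         call. = FALSE)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) readLines(prj, n = 1L) else "local-metric"
  spec <- GridSpec(nr, nc,
                   originX = hdr$xllcorner,
                   originY = hdr$yllcorner + nr * hdr$cellsize,
                   cellSize = hdr$cellsize, crsTag = crs)
  geoRaster(m, spec, nodata = nodata)
}

#' Write a raster as an ESRI ASCII grid file
#'
#' Values are written with 17 significant digits, so a write/read round
#' trip reproduces values and grid geometry bit-exactly. The CRS tag goes
#' to a \code{.prj} sidecar next to the \code{.asc} file.
#'
#' @param raster a [GeoRaster-class].
#' @param path output path (conventionally \code{.asc}).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(raster, path) {
  stopifnot(is(raster, "GeoRaster"))
  spec <- raster@spec
  v <- raster@values
  if (any(v == raster@nodata, na.rm = TRUE))
    stop("raster contains cells equal to its nodata sentinel (", raster@nodata,
         "); choose a different sentinel", call. = FALSE)
  v[is.na(v)] <- raster@nodata
  hdr <- c(
    sprintf("ncols %d", spec@nCols),
    sprintf("nrows %d", spec@nRows),
    sprintf("xllcorner %.17g", spec@originX),
    sprintf("yllcorner %.17g", spec@originY - spec@nRows * spec@cellSize),
    sprintf("cellsize %.17g", spec@cellSize),
    sprintf("NODATA_value %.17g", raster@nodata)
  )
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(spec@crsTag, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

# ---- resampling ----------------------------------------------------------

#' Resample a raster onto a target grid
#'
#' Nearest-neighbour picks the value of the nearest source cell centre (the
#' rule used for the ~1 km nighttime-light and NDVI inputs); bilinear
#' interpolates the four surrounding source centres (the rule used for the
#' DEM), propagating nodata through any contributing cell. Target cells
#' whose centre falls outside the source extent become nodata.
#'
#' @param src source [GeoRaster-class].
#' @param target target [GridSpec-class]; must share the source's CRS tag.
#' @param method \code{"nearest"} or \code{"bilinear"}.
#' @return a [GeoRaster-class] on \code{target}.
#' @export
resampleRaster <- function(src, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is(src, "GeoRaster"), is(target, "GridSpec"))
  if (!identical(src@spec@crsTag, target@crsTag))
    stop("CRS tag mismatch between source ('", src@spec@crsTag,
         "') and target ('", target@crsTag, "')", call. = FALSE)
  s <- src@spec
  tx <- cellCenterX(target); ty <- cellCenterY(target)
  # fractional 1-based cell-centre coordinates in the source grid
  gc <- (tx - s@originX) / s@cellSize + 0.5
  gr <- (s@originY - ty) / s@cellSize + 0.5
  inside <- gc >= 0.5 & gc <= s@nCols + 0.5 & gr >= 0.5 & gr <= s@nRows + 0.5
  if (!any(inside))
    stop("no overlap between source raster and target grid", call. = FALSE)
  out <- matrix(NA_real_, target@nRows, target@nCols)
  v <- src@values
  if (method == "nearest") {
    ri <- pmin(pmax(round(gr), 1), s@nRows)
    ci <- pmin(pmax(round(gc), 1), s@nCols)
    out[inside] <- v[cbind(ri[inside], ci[inside])]
  } else {
    r0 <- floor(gr); c0 <- floor(gc)
    fr <- gr - r0; fc <- gc - c0
    cl <- function(i, n) pmin(pmax(i, 1), n)
    r0c <- cl(r0, s@nRows); r1c <- cl(r0 + 1, s@nRows)
    c0c <- cl(c0, s@nCols); c1c <- cl(c0 + 1, s@nCols)
    w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
    w10 <- fr * (1 - fc);       w11 <- fr * fc
    acc <- matrix(0, target@nRows, target@nCols)
    bad <- matrix(FALSE, target@nRows, target@nCols)
    addTerm <- function(acc, bad, w, rr, cc) {
      val <- v[cbind(as.vector(rr), as.vector(cc))]
      use <- w > 0
      bad <- bad | (use & is.na(val))
      val[!use | is.na(val)] <- 0
      list(acc = acc + w * val, bad = bad)
    }
    for (term in list(list(w00, r0c, c0c), list(w01, r0c, c1c),
                      list(w10, r1c, c0c), list(w11, r1c, c1c))) {
      z <- addTerm(acc, bad, term[[1]], term[[2]], term[[3]])
      acc <- z$acc; bad <- z$bad
    }
    acc[bad] <- NA_real_
    out[inside] <- acc[inside]
  }
  geoRaster(out, target, nodata = src@nodata)
}

# ---- terrain -------------------------------------------------------------

#' Slope in degrees from a DEM (Horn 3x3 method)
#'
#' Computes per-cell slope from the 3x3 finite-difference gradient of
#' Horn's method (the common GIS default). Edge cells use clamped
#' (edge-replicated) neighbourhoods; a cell becomes nodata when any cell of
#' its (clamped) 3x3 neighbourhood is nodata.
#'
#' @param dem [GeoRaster-class] of elevations in metres, on a metric grid.
#' @return [GeoRaster-class] of slope in degrees.
#' @export
slopeFromDem <- function(dem) {
  stopifnot(is(dem, "GeoRaster"))
  cs <- dem@spec@cellSize
  if (!is.finite(cs) || cs <= 0)
    stop("DEM grid must have a positive metric cell size", call. = FALSE)
  z <- dem@values
  nr <- nrow(z); nc <- ncol(z)
  sh <- function(dr, dc) { # shifted matrix with edge replication
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    z[ri, ci, drop = FALSE]
  }
  a <- sh(-1, -1); b <- sh(-1, 0); cc_ <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  dzdx <- ((cc_ + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc_)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(dzdx) | is.na(dzdy) | is.na(z)] <- NA_real_
  geoRaster(slope, dem@spec, nodata = dem@nodata)
}
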