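#' @import methods
NULL

#' Gridded raster layer on a regular square grid
#'
#' Minimal matrix-backed raster container used throughout the package.  All
#' layers of a jurisdiction share the same grid dimensions and pixel size;
#' pixel area is (pixel size)^2 with no projection correction, so a 30 m
#' pixel covers 0.09 ha.
#'
#' @slot values numeric or integer matrix (rows = northing, cols = easting)
#' @slot pixelSize pixel edge length in metres
#' @slot nodata value used to mark no-data pixels on disk
#' @export
setClass("RasterGrid",
  representation(values = "matrix", pixelSize = "numeric", nodata = "numeric"),
  prototype(pixelSize = 30, nodata = -9999)
)

setValidity("RasterGrid", function(object) {
  msg <- NULL
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RasterGrid
#'
#' @param values numeric matrix of cell values
#' @param pixelSize pixel edge length in metres (default 30)
#' @param nodata no-data marker (default -9999)
#' @return a \linkS4class{RasterGrid}
#' @export
RasterGrid <- function(values, pixelSize = 30, nodata = -9999) {
  new("RasterGrid", values = values, pixelSize = pixelSize, nodata = nodata)
}

#' @describeIn RasterGrid cell values as a matrix
#' @param x a RasterGrid
#' @export
gridValues <- function(x) x@values

#' @describeIn RasterGrid pixel edge length in metres
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn RasterGrid area of one pixel in hectares
#' @export
pixelAreaHa <- function(x) x@pixelSize^2 / 1e4

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d pixels @ %g m (%.4g ha/pixel)\n",
              nrow(v), ncol(v), object@pixelSize, pixelAreaHa(object)))
  cat(sprintf("  range: [%g, %g]\n", min(v), max(v)))
})

#' Check that rasters share grid, extent and pixel size
#'
#' @param ... RasterGrid objects
#' @return TRUE invisibly, or an error naming the mismatch
#' @export
checkAligned <- function(...) {
  rs <- list(...)
  ref <- rs[[1L]]
  for (r in rs[-1L]) {
    if (!identical(dim(r@values), dim(ref@values)))
      stop("rasters are misaligned: grid dimensions differ")
    if (!isTRUE(all.equal(r@pixelSize, ref@pixelSize)))
      stop("rasters are misaligned: pixel sizes differ")
  }
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format (NCOLS/NROWS header followed by a
#' row-major value block).  Pixel size is carried in the CELLSIZE field.
#'
#' @param x a \linkS4class{RasterGrid}
#' @param path output file path (conventionally .asc)
#' @export
writeAsciiGrid <- function(x, path) {
  v <- x@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    "XLLCORNER 0", "YLLCORNER 0",
    sprintf("CELLSIZE %g", x@pixelSize),
    sprintf("NODATA_VALUE %g", x@nodata)
  ), con)
  vv <- v
  vv[is.na(vv)] <- x@nodata
  write.table(format(vv, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path file written by \code{\link{writeAsciiGrid}} (or any
#'   conforming ASCII grid)
#' @return a \linkS4class{RasterGrid}; no-data cells become NA
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), toupper(kv[, 1]))
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = h[["NROWS"]], ncol = h[["NCOLS"]], byrow = TRUE)
  m[m == h[["NODATA_VALUE"]]] <- NA
  RasterGrid(m, pixelSize = h[["CELLSIZE"]], nodata = h[["NODATA_VALUE"]])
}
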