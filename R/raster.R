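#' Construct a RasterGrid
#'
#' @param values numeric matrix, first row northernmost; \code{NA} = NODATA.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize cell edge length (> 0).
#' @param nodataValue sentinel written for \code{NA} cells (default -9999).
#' @return a \linkS4class{RasterGrid}.
#' @export
RasterGrid <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 1,
                       nodataValue = -9999) {
  new("RasterGrid", ncols = ncol(values), nrows = nrow(values),
      xllcorner = as.numeric(xllcorner), yllcorner = as.numeric(yllcorner),
      cellsize = as.numeric(cellsize), nodataValue = as.numeric(nodataValue),
      values = values)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file path.
#' @return a \linkS4class{RasterGrid}; NODATA cells become \code{NA}.
#' @export
readAsciiRaster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("ASCII grid header incomplete in %s", path))
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match ncols x nrows")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  RasterGrid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid (.asc)
#'
#' @param raster a \linkS4class{RasterGrid}.
#' @param path output file.
#' @export
writeAsciiRaster <- function(raster, path) {
  m <- raster@values
  m[is.na(m)] <- raster@nodataValue
  hdr <- c(sprintf("ncols %d", raster@ncols),
           sprintf("nrows %d", raster@nrows),
           sprintf("xllcorner %.10g", raster@xllcorner),
           sprintf("yllcorner %.10g", raster@yllcorner),
           sprintf("cellsize %.10g", raster@cellsize),
           sprintf("NODATA_value %.10g", raster@nodataValue))
  rows <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Extract raster values at point locations
#'
#' Each point is assigned the value of the cell containing it; cell
#' membership uses half-open intervals
#' \code{[xll + j*cellsize, xll + (j+1)*cellsize)} in both axes, so a point on
#' a shared edge belongs to the higher-index (east/north) cell.
#'
#' @param raster a \linkS4class{RasterGrid}.
#' @param x,y point coordinates (same length).
#' @return numeric vector of cell values; NODATA cells give \code{NA} with a
#'   warning naming the points.
#' @export
extractAtPoints <- function(raster, x, y) {
  stopifnot(length(x) == length(y))
  cs <- raster@cellsize
  col <- floor((x - raster@xllcorner) / cs) + 1
  rowFromS <- floor((y - raster@yllcorner) / cs) + 1 # 1 = southernmost
  oob <- col < 1 | col > raster@ncols | rowFromS < 1 | rowFromS > raster@nrows
  if (any(oob)) {
    k <- which(oob)[1L]
    stop(sprintf("point (%g, %g) outside raster bounds", x[k], y[k]))
  }
  row <- raster@nrows - rowFromS + 1 # matrix row 1 is northernmost
  vals <- raster@values[cbind(row, col)]
  if (anyNA(vals))
    warning(sprintf("%d point(s) fall on NODATA cells", sum(is.na(vals))))
  vals
}
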