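## Grid constructors, accessors and plain-text I/O.

#' Create a continuous raster grid
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` marks missing
#'   cells.
#' @param xll,yll coordinates of the lower-left grid corner (m).
#' @param cellsize cell edge length (m).
#' @param units value units string.
#' @return A [RasterGrid-class].
#' @examples
#' g <- rasterGrid(matrix(1:6, 2), cellsize = 250, units = "m")
#' gridValues(g)
#' @export
rasterGrid <- function(values, xll = 0, yll = 0, cellsize = 250, units = "") {
  new("RasterGrid", values = values, xll = as.numeric(xll),
      yll = as.numeric(yll), cellsize = as.numeric(cellsize), units = units)
}

#' Create a categorical raster grid
#'
#' @param codes integer matrix of category codes, `NA` for missing.
#' @param legend named character vector: names are codes (as character),
#'   values are labels.
#' @inheritParams rasterGrid
#' @return A [CategoricalGrid-class].
#' @export
categoricalGrid <- function(codes, legend, xll = 0, yll = 0, cellsize = 250) {
  storage.mode(codes) <- "integer"
  new("CategoricalGrid", codes = codes, legend = legend,
      xll = as.numeric(xll), yll = as.numeric(yll),
      cellsize = as.numeric(cellsize))
}

#' @describeIn rasterGrid Extract the value matrix.
#' @param x a grid object.
#' @export
gridValues <- function(x) {
  if (is(x, "RasterGrid")) x@values else x@codes
}

#' Grid geometry accessors
#'
#' @param x a [RasterGrid-class] or [CategoricalGrid-class].
#' @return `cellSize`: the cell edge length (m); `gridUnits`: the value units;
#'   `gridLegend`: the legend of a categorical grid.
#' @export
cellSize <- function(x) x@cellsize

#' @rdname cellSize
#' @export
gridUnits <- function(x) x@units

#' @rdname cellSize
#' @export
gridLegend <- function(x) x@legend

#' Do two grids share the same geometry?
#'
#' Same shape, origin and cell size (1e-6 m tolerance). The pipeline refuses
#' to combine layers that are not co-registered rather than resampling
#' silently.
#'
#' @param a,b grid objects.
#' @return logical.
#' @export
sameGeometry <- function(a, b) {
  va <- gridValues(a); vb <- gridValues(b)
  all(dim(va) == dim(vb)) &&
    abs(a@xll - b@xll) < 1e-6 && abs(a@yll - b@yll) < 1e-6 &&
    abs(a@cellsize - b@cellsize) < 1e-6
}

.stopIfMisaligned <- function(a, b, what = "layers") {
  if (!sameGeometry(a, b))
    stop(sprintf(
      "%s are not co-registered: [%d x %d, xll=%g, yll=%g, cs=%g] vs [%d x %d, xll=%g, yll=%g, cs=%g]",
      what, nrow(gridValues(a)), ncol(gridValues(a)), a@xll, a@yll, a@cellsize,
      nrow(gridValues(b)), ncol(gridValues(b)), b@xll, b@yll, b@cellsize),
      call. = FALSE)
  invisible(TRUE)
}

#' Map coordinates to cell row/column
#'
#' Pixels are half-open: a cell covers `[x, x + cs)` horizontally and
#' `(y - cs, y]` vertically, so a point on the shared edge of two cells
#' belongs to the cell to its east (x) and below (y). Points on the bottom
#' or left extent boundary are taken into the first row/column.
#'
#' @param grid a grid object.
#' @param x,y numeric coordinate vectors.
#' @return data.frame with columns row, col (`NA` outside the extent).
#' @export
cellIndex <- function(grid, x, y) {
  v <- gridValues(grid)
  nr <- nrow(v); nc <- ncol(v); cs <- grid@cellsize
  col <- floor((x - grid@xll) / cs) + 1L
  rowFromBottom <- ceiling((y - grid@yll) / cs)
  rowFromBottom[rowFromBottom == 0L & y >= grid@yll - 1e-9] <- 1L
  row <- nr - rowFromBottom + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates of every grid cell
#'
#' @param grid a grid object.
#' @return data.frame (row, col, x, y), row-major over the grid.
#' @export
cellCenters <- function(grid) {
  v <- gridValues(grid)
  nr <- nrow(v); nc <- ncol(v); cs <- grid@cellsize
  ij <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  data.frame(row = ij$row, col = ij$col,
             x = grid@xll + (ij$col - 0.5) * cs,
             y = grid@yll + (nr - ij$row + 0.5) * cs)
}

## ---------------------------------------------------------------------------
## ESRI ASCII grid I/O (plain text, hand-parsed: no raster package available)
## ---------------------------------------------------------------------------

#' Read / write grids as ESRI ASCII text rasters
#'
#' Single-band plain-text raster exchange format: a six-line header (ncols,
#' nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of
#' values, north to south. Categorical grids carry their legend in a JSON
#' sidecar file `<path>.legend.json`.
#'
#' @param path file path (conventionally `.asc`).
#' @param units value units to attach on read.
#' @return `readAsciiGrid` returns a [RasterGrid-class];
#'   `readCategoricalGrid` a [CategoricalGrid-class]. Writers return the path
#'   invisibly.
#' @export
readAsciiGrid <- function(path, units = "") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  rasterGrid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cellsize = hdr$cellsize, units = units)
}

#' @rdname readAsciiGrid
#' @param grid grid object to write.
#' @param nodata sentinel written for `NA` cells.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  v <- gridValues(grid)
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid@xll),
           sprintf("yllcorner %.10g", grid@yll),
           sprintf("cellsize %.10g", grid@cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname readAsciiGrid
#' @export
writeCategoricalGrid <- function(grid, path, nodata = -9999) {
  writeAsciiGrid(rasterGrid(grid@codes + 0, grid@xll, grid@yll,
                            grid@cellsize), path, nodata = nodata)
  jsonlite::write_json(as.list(grid@legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname readAsciiGrid
#' @export
readCategoricalGrid <- function(path) {
  g <- readAsciiGrid(path)
  legend <- unlist(jsonlite::read_json(paste0(path, ".legend.json")))
  categoricalGrid(g@values, legend, g@xll, g@yll, g@cellsize)
}

## show methods -------------------------------------------------------------

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("RasterGrid %d x %d, cell %g m, units '%s'\n",
              nrow(v), ncol(v), object@cellsize, object@units))
  cat(sprintf("  range [%g, %g], %d NA cells\n",
              rng[1], rng[2], sum(is.na(v))))
})

setMethod("show", "CategoricalGrid", function(object) {
  cat(sprintf("CategoricalGrid %d x %d, cell %g m, %d classes\n",
              nrow(object@codes), ncol(object@codes), object@cellsize,
              length(object@legend)))
  tab <- table(factor(as.vector(object@codes), levels = names(object@legend),
                      labels = object@legend))
  print(tab)
})
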