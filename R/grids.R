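#' Create a GridSpec
#'
#' @param minLon,minLat south-west corner, degrees.
#' @param cellSize cell edge in degrees; default 0.25 (roughly 30 km).
#' @param nRows,nCols lattice dimensions.
#' @param crs geographic CRS identifier (informational).
#' @return a [GridSpec-class].
#' @examples
#' g <- gridSpec(0, 0, 0.25, 4, 4)
#' pointToCell(g, 0.3, 0.1)
#' @export
gridSpec <- function(minLon, minLat, cellSize = 0.25, nRows, nCols,
                     crs = "EPSG:4326") {
  new("GridSpec", minLon = as.numeric(minLon), minLat = as.numeric(minLat),
      cellSize = as.numeric(cellSize), nRows = as.integer(nRows),
      nCols = as.integer(nCols), crs = crs)
}

#' Number of cells of a grid
#' @param grid a [GridSpec-class].
#' @return integer.
#' @export
nCells <- function(grid) grid@nRows * grid@nCols

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d rows x %d cols, cell %g deg, origin (%g, %g), %s\n",
              object@nRows, object@nCols, object@cellSize,
              object@minLon, object@minLat, object@crs))
})

#' Map points to grid cells
#'
#' Half-open lower-inclusive assignment: a point on a cell's southern or
#' western edge belongs to that cell. Points outside the grid extent map
#' to `NA` (the outside marker).
#'
#' @param grid a [GridSpec-class].
#' @param lon,lat numeric vectors of coordinates (degrees); must be
#'   finite.
#' @return integer vector of 1-based linear cell indices, `NA` outside.
#' @export
pointToCell <- function(grid, lon, lat) {
  if (length(lon) != length(lat))
    stop("lon and lat must have equal length")
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates passed to pointToCell")
  col0 <- floor((lon - grid@minLon) / grid@cellSize)
  row0 <- floor((lat - grid@minLat) / grid@cellSize)
  out <- col0 < 0 | col0 >= grid@nCols | row0 < 0 | row0 >= grid@nRows
  idx <- as.integer(row0 * grid@nCols + col0 + 1)
  idx[out] <- NA_integer_
  idx
}

#' Row/column address of linear cell indices
#' @param grid a [GridSpec-class].
#' @param cell integer linear indices.
#' @return data.frame with columns `row`, `col` (1-based, row 1 south).
#' @export
cellRowCol <- function(grid, cell) {
  row <- (cell - 1L) %/% grid@nCols + 1L
  col <- (cell - 1L) %% grid@nCols + 1L
  data.frame(row = row, col = col)
}

#' Centre coordinates of grid cells
#' @param grid a [GridSpec-class].
#' @param cell integer linear indices.
#' @return data.frame with columns `lon`, `lat`.
#' @export
cellCenter <- function(grid, cell) {
  rc <- cellRowCol(grid, cell)
  data.frame(lon = grid@minLon + (rc$col - 0.5) * grid@cellSize,
             lat = grid@minLat + (rc$row - 0.5) * grid@cellSize)
}

#' Create a RasterLayer
#' @param grid a [GridSpec-class].
#' @param values numeric vector of length `nCells(grid)` in linear cell
#'   order; `NA` = nodata. A single value is recycled.
#' @param name layer name.
#' @return a [RasterLayer-class].
#' @export
rasterLayer <- function(grid, values, name = "layer") {
  if (length(values) == 1) values <- rep(as.numeric(values), nCells(grid))
  new("RasterLayer", grid = grid, name = name, values = as.numeric(values))
}

#' @describeIn rasterLayer per-cell values (NA = nodata).
#' @param x a [RasterLayer-class].
#' @export
layerValues <- function(x) x@values

#' @describeIn rasterLayer logical nodata mask (`TRUE` = nodata).
#' @export
nodataMask <- function(x) is.na(x@values)

setMethod("show", "RasterLayer", function(object) {
  v <- object@values
  cat(sprintf("RasterLayer '%s' on %dx%d grid: %d valid cells",
              object@name, object@grid@nRows, object@grid@nCols,
              sum(!is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf(", range [%.4g, %.4g]", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  cat("\n")
})

#' Create a RasterStack
#' @param layers a list of [RasterLayer-class] on one grid; names taken
#'   from the layers when the list is unnamed.
#' @return a [RasterStack-class].
#' @export
rasterStack <- function(layers) {
  if (!length(layers)) stop("a RasterStack needs at least one layer")
  if (is.null(names(layers)))
    names(layers) <- vapply(layers, function(l) l@name, character(1))
  new("RasterStack", grid = layers[[1]]@grid, layers = layers)
}

#' @describeIn rasterStack layer names.
#' @param x a [RasterStack-class].
#' @export
layerNames <- function(x) names(x@layers)

#' @describeIn rasterStack cells-by-layers numeric matrix of values.
#' @export
stackValues <- function(x) {
  vapply(x@layers, layerValues, numeric(nCells(x@grid)))
}

#' @describeIn rasterStack subset a stack by layer names, keeping order.
#' @param names character, layers to keep.
#' @export
subsetStack <- function(x, names) {
  missing <- setdiff(names, layerNames(x))
  if (length(missing))
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  rasterStack(x@layers[names])
}

setMethod("show", "RasterStack", function(object) {
  cat(sprintf("RasterStack: %d layer(s) on %dx%d grid\n  %s\n",
              length(object@layers), object@grid@nRows,
              object@grid@nCols,
              paste(layerNames(object), collapse = ", ")))
})

## ---- plain-grid text IO ----------------------------------------------------

#' Read and write gridded layers
#'
#' The native on-disk format is a plain text grid: a header line
#' `n_rows n_cols min_lon min_lat cell_size nodata`, a second line
#' `name <layer name>`, then `n_rows` lines of `n_cols` values, the
#' southernmost row first, nodata written as the header token. Values
#' round-trip to better than 1e-9. Other raster formats (e.g. GeoTIFF)
#' are rejected with an explicit unsupported-format error.
#'
#' @param path file path; extensions `.grd` and `.txt` are accepted.
#' @param layer a [RasterLayer-class].
#' @param crs CRS recorded on the grid of the layer read back.
#' @return `readRaster` returns a [RasterLayer-class]; `writeRaster`
#'   returns `path` invisibly.
#' @export
readRaster <- function(path, crs = "EPSG:4326") {
  checkGridExtension(path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- strsplit(trimws(readLines(con, n = 1)), "\\s+")[[1]]
  if (length(hdr) != 6)
    stop("malformed grid header in ", path)
  nRows <- as.integer(hdr[1]); nCols <- as.integer(hdr[2])
  nodata <- hdr[6]
  nameLine <- strsplit(readLines(con, n = 1), "\\s+")[[1]]
  name <- if (length(nameLine) >= 2) paste(nameLine[-1], collapse = " ")
          else "layer"
  vals <- scan(con, what = character(), n = nRows * nCols, quiet = TRUE)
  v <- suppressWarnings(as.numeric(vals))
  v[vals == nodata] <- NA_real_
  grid <- gridSpec(as.numeric(hdr[3]), as.numeric(hdr[4]),
                   as.numeric(hdr[5]), nRows, nCols, crs = crs)
  rasterLayer(grid, v, name = name)
}

#' @rdname readRaster
#' @export
writeRaster <- function(layer, path) {
  checkGridExtension(path)
  g <- layer@grid
  nodata <- "NA"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d %s %s %s %s", g@nRows, g@nCols,
                     fmtNum(g@minLon), fmtNum(g@minLat),
                     fmtNum(g@cellSize), nodata), con)
  writeLines(paste("name", layer@name), con)
  v <- fmtNum(layer@values)
  v[is.na(layer@values)] <- nodata
  m <- matrix(v, nrow = g@nRows, ncol = g@nCols, byrow = TRUE)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

fmtNum <- function(x) formatC(x, digits = 17, format = "g", width = -1)

checkGridExtension <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff", "nc", "img", "asc"))
    stop("unsupported raster format '.", ext,
         "'; the package reads and writes plain-grid text (.grd/.txt)")
  invisible(path)
}

## ---- aggregation / cropping / projection -----------------------------------

#' Aggregate a fine layer to a coarser aligned grid
#'
#' Each coarse cell becomes the unweighted arithmetic mean of its
#' contributing non-nodata fine cells; a coarse cell is nodata only when
#' all contributors are nodata. The coarse cell size must be an integer
#' multiple of the fine cell size and the origins must coincide.
#'
#' @param fine a [RasterLayer-class].
#' @param coarse a [GridSpec-class] covering the same extent.
#' @return a [RasterLayer-class] on `coarse`.
#' @export
aggregateToGrid <- function(fine, coarse) {
  gf <- fine@grid
  r <- coarse@cellSize / gf@cellSize
  if (abs(r - round(r)) > 1e-9)
    stop("coarse cell size must be an integer multiple of the fine cell size")
  r <- as.integer(round(r))
  if (abs(gf@minLon - coarse@minLon) > 1e-9 ||
      abs(gf@minLat - coarse@minLat) > 1e-9)
    stop("grids must share an origin")
  if (gf@nRows != coarse@nRows * r || gf@nCols != coarse@nCols * r)
    stop("coarse grid extent does not match the fine grid")
  idx <- seq_len(nCells(gf))
  rowF <- (idx - 1L) %/% gf@nCols
  colF <- (idx - 1L) %% gf@nCols
  coarseIdx <- (rowF %/% r) * coarse@nCols + (colF %/% r) + 1L
  v <- fine@values
  sums <- rowsum(ifelse(is.na(v), 0, v), coarseIdx)
  cnts <- rowsum(as.numeric(!is.na(v)), coarseIdx)
  out <- as.numeric(sums / cnts)   # NaN where no valid contributor
  out[cnts == 0] <- NA_real_
  rasterLayer(coarse, out[order(as.integer(rownames(sums)))],
              name = fine@name)
}

#' Extract an aligned sub-grid from a layer or stack
#'
#' @param x a [RasterLayer-class] or [RasterStack-class].
#' @param sub a [GridSpec-class] with the same cell size, aligned to and
#'   contained in the extent of `x`.
#' @return object of the same class as `x`, on `sub`.
#' @export
cropToGrid <- function(x, sub) {
  if (is(x, "RasterStack"))
    return(rasterStack(lapply(x@layers, cropToGrid, sub = sub)))
  g <- x@grid
  if (abs(g@cellSize - sub@cellSize) > 1e-9)
    stop("cropToGrid requires equal cell sizes")
  offC <- (sub@minLon - g@minLon) / g@cellSize
  offR <- (sub@minLat - g@minLat) / g@cellSize
  if (abs(offC - round(offC)) > 1e-6 || abs(offR - round(offR)) > 1e-6)
    stop("sub-grid is not aligned to the parent lattice")
  ctr <- cellCenter(sub, seq_len(nCells(sub)))
  parent <- pointToCell(g, ctr$lon, ctr$lat)
  if (anyNA(parent))
    stop("sub-grid extends outside the parent grid")
  rasterLayer(sub, x@values[parent], name = x@name)
}

#' Project a layer onto another grid by nearest-cell lookup
#'
#' Each target cell takes the value of the source cell containing its
#' centre (identity when the lattices coincide); target cells whose
#' centres fall outside the source extent become nodata.
#'
#' @param layer a [RasterLayer-class].
#' @param target a [GridSpec-class].
#' @return a [RasterLayer-class] on `target`.
#' @export
projectLayer <- function(layer, target) {
  ctr <- cellCenter(target, seq_len(nCells(target)))
  src <- pointToCell(layer@grid, ctr$lon, ctr$lat)
  v <- rep(NA_real_, nCells(target))
  ok <- !is.na(src)
  v[ok] <- layer@values[src[ok]]
  rasterLayer(target, v, name = layer@name)
}
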