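#' Create a geographic grid
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xmin western edge (decimal degrees).
#' @param ymax northern edge (decimal degrees).
#' @param cellsize cell size in decimal degrees.
#' @return A \linkS4class{GeoGrid}.
#' @examples
#' g <- geoGrid(matrix(1:6, 2, 3), xmin = 110, ymax = 30, cellsize = 0.5)
#' gridValues(g)[1, 1]
#' @export
geoGrid <- function(values, xmin, ymax, cellsize) {
  storage.mode(values) <- "double"
  new("GeoGrid", values = values, xmin = xmin, ymax = ymax,
      cellsize = cellsize)
}

#' @describeIn geoGrid the value matrix.
#' @param x a GeoGrid.
#' @export
gridValues <- function(x) x@values

#' @describeIn geoGrid geometry as a named list (xmin, ymax, cellsize,
#'   nrow, ncol, xmax, ymin).
#' @export
gridGeometry <- function(x) {
  d <- dim(x@values)
  list(xmin = x@xmin, ymax = x@ymax, cellsize = x@cellsize,
       nrow = d[1], ncol = d[2],
       xmax = x@xmin + d[2] * x@cellsize,
       ymin = x@ymax - d[1] * x@cellsize)
}

sameGeometry <- function(a, b, tol = 1e-9) {
  ga <- gridGeometry(a); gb <- gridGeometry(b)
  ga$nrow == gb$nrow && ga$ncol == gb$ncol &&
    abs(ga$xmin - gb$xmin) < tol && abs(ga$ymax - gb$ymax) < tol &&
    abs(ga$cellsize - gb$cellsize) < tol
}

setMethod("show", "GeoGrid", function(object) {
  g <- gridGeometry(object)
  v <- object@values
  cat(sprintf("GeoGrid: %d x %d cells of %g deg, extent [%g, %g] x [%g, %g]\n",
              g$nrow, g$ncol, g$cellsize, g$xmin, g$xmax, g$ymin, g$ymax))
  cat(sprintf("  values: %d valid, range [%g, %g]\n",
              sum(!is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

#' Map points to cells and back
#'
#' Cells are indexed row-major starting at the north-west corner
#' (cell 1 = row 1, column 1). A point belongs to the cell whose
#' half-open intervals \eqn{[west, east) \times (south, north]} contain
#' it; points outside the extent map to \code{NA}.
#'
#' @param grid a \linkS4class{GeoGrid}.
#' @param x,y longitude and latitude vectors.
#' @return \code{cellFromXY}: integer cell indices; \code{xyFromCell}: a
#'   two-column matrix of cell-centre coordinates.
#' @export
cellFromXY <- function(grid, x, y) {
  g <- gridGeometry(grid)
  # snap near-integer offsets so cell edges land on the convention
  # ([west, east) x (south, north]) despite floating-point division
  snapFloor <- function(u, eps = 1e-9) {
    r <- round(u)
    ifelse(abs(u - r) < eps, r, floor(u))
  }
  col <- snapFloor((x - g$xmin) / g$cellsize) + 1
  row <- snapFloor((g$ymax - y) / g$cellsize) + 1
  # north edge of the grid belongs to row 1 under (south, north]
  row[row == 0 & !is.na(row)] <- 1L
  ok <- !is.na(col) & !is.na(row) &
    col >= 1 & col <= g$ncol & row >= 1 & row <= g$nrow
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((row[ok] - 1) * g$ncol + col[ok])
  out
}

#' @rdname cellFromXY
#' @param cell integer cell indices.
#' @export
xyFromCell <- function(grid, cell) {
  g <- gridGeometry(grid)
  row <- (cell - 1) %/% g$ncol + 1
  col <- (cell - 1) %% g$ncol + 1
  cbind(x = g$xmin + (col - 0.5) * g$cellsize,
        y = g$ymax - (row - 0.5) * g$cellsize)
}

#' @rdname cellFromXY
#' @export
valuesAtCells <- function(grid, cell) {
  g <- gridGeometry(grid)
  row <- (cell - 1) %/% g$ncol + 1
  col <- (cell - 1) %% g$ncol + 1
  grid@values[cbind(row, col)]
}

#' Read and write ESRI ASCII grids
#'
#' The plain-text single-band grid format (ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value header followed by rows north to
#' south).
#'
#' @param file path to a .asc file.
#' @return \code{readAsciiGrid}: a \linkS4class{GeoGrid}.
#' @export
readAsciiGrid <- function(file) {
  lines <- readLines(file)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  geoGrid(m, xmin = hdr$xllcorner,
          ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
          cellsize = hdr$cellsize)
}

#' @rdname readAsciiGrid
#' @param grid a \linkS4class{GeoGrid} to write.
#' @param nodata sentinel written for \code{NA} cells.
#' @export
writeAsciiGrid <- function(grid, file, nodata = -9999) {
  g <- gridGeometry(grid)
  v <- grid@values
  v[is.na(v)] <- nodata
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10g", g$xmin), sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}
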