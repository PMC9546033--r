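#' Define a projected 1-km analysis grid
#'
#' A `grid_spec` describes a regular raster grid in projected metric
#' coordinates.  Cell `(i, j)` (1-based, row 1 at the top) covers the square
#' `[origin_x + (j-1)*cs, origin_x + j*cs)` in x and, by the floor
#' convention used throughout the package, contains every point `y` with
#' `floor((origin_y - y)/cs) == i - 1`.  `origin_y` is the *top* edge of the
#' grid.
#'
#' @param origin_x,origin_y coordinates (m) of the top-left grid corner.
#' @param cell_size cell edge length in metres (default 1000, i.e. 1 km).
#' @param n_rows,n_cols grid dimensions.
#' @param crs_label opaque CRS tag carried through to raster headers.
#' @param nodata sentinel value used when rasters are written to disk.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 100000, 1000, 100, 100)
#' cell_of(c(500, 1500), c(99500, 99500), g)
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, cell_size = 1000,
                      n_rows = 1, n_cols = 1, crs_label = "EPSG:3035",
                      nodata = -9999) {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), crs_label = crs_label,
                 nodata = nodata),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m (origin %g, %g; %s)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

#' Map point coordinates to grid cells
#'
#' Uses floor arithmetic on `(x - origin_x)/cell_size` and
#' `(origin_y - y)/cell_size`, the single point-in-cell convention shared by
#' background sampling, checkerboard partitioning and SWD extraction.
#'
#' @param x,y numeric vectors of projected coordinates (m).
#' @param grid a [grid_spec()].
#' @return a data.frame with columns `row`, `col` (1-based; `NA` outside the
#'   grid) and `cell` (linear index, column-major).
#' @export
cell_of <- function(x, y, grid) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  bad <- row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols |
    !is.finite(row) | !is.finite(col)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer(row + (col - 1) * grid$n_rows))
}

#' Coordinates of cell centres
#' @param row,col 1-based cell indices.
#' @param grid a [grid_spec()].
#' @return data.frame with `x`, `y` of the cell centres.
#' @export
cell_center <- function(row, col, grid) {
  data.frame(x = grid$origin_x + (col - 0.5) * grid$cell_size,
             y = grid$origin_y - (row - 0.5) * grid$cell_size)
}

#' Create a single-band raster layer on a grid
#'
#' @param grid a [grid_spec()].
#' @param name variable name (e.g. `"bio1"`, `"elevation"`).
#' @param values numeric matrix (`n_rows` x `n_cols`); `NA` marks nodata.
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(grid, name, values) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
    stop("values shape does not match grid (", grid$n_rows, " x ",
         grid$n_cols, ")")
  structure(list(grid = grid, name = name, values = values),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("raster_layer '%s': %d x %d, range [%.4g, %.4g], %d nodata\n",
              x$name, nrow(x$values), ncol(x$values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(!is.finite(x$values))))
  invisible(x)
}

#' Extract cell values at point locations
#' @param layer a [raster_layer()].
#' @param x,y point coordinates.
#' @return numeric vector (`NA` outside the grid or on nodata cells).
#' @export
extract_at <- function(layer, x, y) {
  idx <- cell_of(x, y, layer$grid)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- layer$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("origin_x", "origin_y", "cell_size")],
                   b[c("origin_x", "origin_y", "cell_size")])) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster dialect (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' one line per row, top row first.  Readable by GDAL, QGIS and terra.
#'
#' @param layer a [raster_layer()].
#' @param path output file path.
#' @export
write_ascii_grid <- function(layer, path) {
  g <- layer$grid
  v <- layer$values
  v[!is.finite(v)] <- g$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata)), con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#' @param path file path.
#' @param name variable name for the returned layer (default: file stem).
#' @param crs_label CRS tag to attach.
#' @return a [raster_layer()].
#' @export
read_ascii_grid <- function(path, name = NULL,
                            crs_label = "EPSG:3035") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- as.numeric(kv[, 2])
  names(val) <- tolower(kv[, 1])
  g <- grid_spec(origin_x = val[["xllcorner"]],
                 origin_y = val[["yllcorner"]] +
                   val[["nrows"]] * val[["cellsize"]],
                 cell_size = val[["cellsize"]],
                 n_rows = val[["nrows"]], n_cols = val[["ncols"]],
                 crs_label = crs_label, nodata = val[["nodata_value"]])
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == g$nodata] <- NA_real_
  raster_layer(g, name %||% sub("\\.[^.]*$", "", basename(path)), m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
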