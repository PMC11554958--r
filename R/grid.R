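#' Analysis grid
#'
#' A regular raster grid in a projected metric coordinate system. Row 1 is
#' the northernmost row: `origin_x`/`origin_y` are the coordinates of the
#' grid's north-west corner, and cell (r, c) has its center at
#' `(origin_x + (c - 0.5) * resolution, origin_y - (r - 0.5) * resolution)`.
#' All area accounting uses the cell area `resolution^2` (0.09 ha at the
#' default 30 m).
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param resolution cell size in meters (default 30).
#' @param origin_x,origin_y north-west corner coordinates (m).
#' @param crs opaque tag naming the metric projection.
#' @return an object of class `bs_grid`.
#' @export
landscape_grid <- function(n_rows, n_cols, resolution = 30,
                           origin_x = 0, origin_y = n_rows * resolution,
                           crs = "local-metric") {
  stopifnot(resolution > 0, n_rows >= 1, n_cols >= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 resolution = resolution, origin_x = origin_x,
                 origin_y = origin_y, crs = crs),
            class = "bs_grid")
}

#' @export
print.bs_grid <- function(x, ...) {
  cat(sprintf("<bs_grid> %d x %d cells @ %g m (%.1f x %.1f km), origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$resolution,
              x$n_cols * x$resolution / 1000, x$n_rows * x$resolution / 1000,
              x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell area of a grid in hectares
#' @param grid a `bs_grid`.
#' @export
cell_area_ha <- function(grid) grid$resolution^2 / 1e4

#' Cell-center coordinates
#'
#' @param grid a `bs_grid`.
#' @return `cell_centers_x` gives the x coordinate of each column,
#'   `cell_centers_y` the y coordinate of each row (row 1 northernmost).
#' @export
cell_centers_x <- function(grid)
  grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$resolution

#' @rdname cell_centers_x
#' @export
cell_centers_y <- function(grid)
  grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$resolution

#' Map coordinates to cell indices
#'
#' @param grid a `bs_grid`.
#' @param x,y coordinate vectors.
#' @return data.frame with integer columns `row`, `col`; NA outside the grid.
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$resolution) + 1
  row <- floor((grid$origin_y - y) / grid$resolution) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

grid_same <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$resolution, b$resolution)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}

new_raster <- function(grid, value = 0) {
  matrix(value, nrow = grid$n_rows, ncol = grid$n_cols)
}
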