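#' Georeferenced single-band raster grid
#'
#' `dem_grid()` wraps a numeric matrix with planar georeferencing: a cell
#' size in metres and the coordinates of the outer upper-left corner.
#' Row 1 is the northernmost row; cell centres sit at
#' `(origin_x + (col - 0.5) * cell, origin_y - (row - 0.5) * cell)`.
#' Missing data are stored as `NA` and never participate in statistics.
#'
#' @param values Numeric matrix of cell values (elevation in metres for a
#'   terrain model, but any single-band layer can be carried).
#' @param cell_size_m Positive cell size in metres (square cells).
#' @param origin_xy Length-2 numeric, planar coordinates of the outer
#'   upper-left corner of the grid.
#' @param layer Character name describing what the values are.
#'
#' @return An object of class `dem_grid`.
#' @export
#'
#' @examples
#' g <- dem_grid(matrix(1:12, 3, 4), cell_size_m = 0.5)
#' dim(g)
#' as_tibble(g)
dem_grid <- function(values, cell_size_m = 0.5, origin_xy = c(0, 0),
                     layer = "elevation") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0) {
    stop("`cell_size_m` must be a single positive number", call. = FALSE)
  }
  if (length(origin_xy) != 2 || !is.numeric(origin_xy)) {
    stop("`origin_xy` must be two planar coordinates", call. = FALSE)
  }
  structure(
    list(
      values = values,
      cell_size_m = as.numeric(cell_size_m),
      origin_xy = as.numeric(origin_xy),
      layer = layer
    ),
    class = "dem_grid"
  )
}

#' @export
dim.dem_grid <- function(x) dim(x$values)

#' @export
print.dem_grid <- function(x, ...) {
  d <- dim(x$values)
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf(
    "<dem_grid> %s: %d x %d cells, %.3g m cell, origin (%.6g, %.6g)\n",
    x$layer, d[1], d[2], x$cell_size_m, x$origin_xy[1], x$origin_xy[2]
  ))
  if (all(is.finite(rng))) {
    cat(sprintf("  values in [%.6g, %.6g], %d NA\n",
                rng[1], rng[2], sum(is.na(x$values))))
  } else {
    cat("  all values NA\n")
  }
  invisible(x)
}

#' Replace the value matrix of a grid, keeping its georeferencing
#' @param grid A [dem_grid()].
#' @param values New matrix with the same dimensions.
#' @param layer Optional new layer name.
#' @return A `dem_grid`.
#' @export
grid_like <- function(grid, values, layer = grid$layer) {
  stopifnot(inherits(grid, "dem_grid"))
  if (!identical(dim(values), dim(grid$values))) {
    stop("replacement values must match the grid dimensions", call. = FALSE)
  }
  dem_grid(values, grid$cell_size_m, grid$origin_xy, layer = layer)
}

#' Planar coordinates of every cell centre
#' @param grid A [dem_grid()].
#' @return List with vectors `x` (per column) and `y` (per row).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "dem_grid"))
  d <- dim(grid$values)
  list(
    x = grid$origin_xy[1] + (seq_len(d[2]) - 0.5) * grid$cell_size_m,
    y = grid$origin_xy[2] - (seq_len(d[1]) - 0.5) * grid$cell_size_m
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long-format view of a raster grid
#'
#' One row per cell with its centre coordinates, suitable for ggplot2 and
#' dplyr work.
#'
#' @param x A [dem_grid()].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `row`, `col`, `value`.
#' @method as_tibble dem_grid
#' @export
as_tibble.dem_grid <- function(x, ...) {
  d <- dim(x$values)
  cc <- grid_coords(x)
  tibble::tibble(
    x = rep(cc$x, each = d[1]),
    y = rep(cc$y, times = d[2]),
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(x$values)
  )
}

#' Raster heat map of a grid
#'
#' @param object A [dem_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dem_grid
#' @export
autoplot.dem_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$layer) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

cell_area_m2 <- function(grid) grid$cell_size_m^2

#' Convert planar coordinates to (row, col) indices
#' @param grid A [dem_grid()].
#' @param x,y Planar coordinates.
#' @return Integer matrix with columns `row`, `col`; coordinates outside the
#'   grid give `NA`.
#' @export
xy_to_cell <- function(grid, x, y) {
  stopifnot(inherits(grid, "dem_grid"))
  d <- dim(grid$values)
  col <- floor((x - grid$origin_xy[1]) / grid$cell_size_m) + 1
  row <- floor((grid$origin_xy[2] - y) / grid$cell_size_m) + 1
  bad <- row < 1 | row > d[1] | col < 1 | col > d[2]
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}
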