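#' Disc structuring element
#'
#' All integer pixel offsets `(dx, dy)` with `sqrt(dx^2 + dy^2) <=
#' diameter_px / 2`. A diameter of 7 pixels (3.5 m at 0.5 m cells) gives a
#' 37-pixel disc; diameters from 5 to 10 pixels are the range worth
#' exploring for hearth-sized platforms, 7 the default used throughout.
#'
#' @param diameter_px Odd positive integer diameter in pixels.
#' @return Object of class `structuring_element`: a list with the offset
#'   matrix (`dr`, `dc` columns) and the diameter.
#' @export
#'
#' @examples
#' nrow(disc_element(7)$offsets)  # 37
disc_element <- function(diameter_px = 7) {
  if (length(diameter_px) != 1 || diameter_px < 1 || diameter_px %% 2 != 1) {
    stop("diameter_px must be an odd positive integer", call. = FALSE)
  }
  r <- diameter_px / 2
  h <- floor(r)
  off <- expand.grid(dr = -h:h, dc = -h:h)
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  structure(
    list(offsets = as.matrix(off), diameter_px = as.integer(diameter_px)),
    class = "structuring_element"
  )
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> disc, diameter %d px, %d pixels\n",
              x$diameter_px, nrow(x$offsets)))
  invisible(x)
}

morph_filter <- function(values, element, which = c("max", "min")) {
  which <- match.arg(which)
  fill <- if (which == "max") -Inf else Inf
  v <- values
  v[is.na(v)] <- fill  # nodata never wins a max/min
  out <- matrix(fill, nrow(v), ncol(v))
  f <- if (which == "max") pmax else pmin
  for (k in seq_len(nrow(element$offsets))) {
    out <- f(out, shift_mat(v, element$offsets[k, 1], element$offsets[k, 2]))
  }
  out[!is.finite(out)] <- NA  # whole window was nodata
  out
}

#' Grayscale dilation, erosion and closing
#'
#' Moving maximum (dilation) and minimum (erosion) under a structuring
#' element, and their composition dilate-then-erode (closing). Borders are
#' handled by edge replication, so no artificial rim appears at the raster
#' edge; nodata cells are excluded from both filters. Closing a slope
#' raster fills narrow low-slope notches smaller than the element,
#' homogenising flat platforms while leaving their steep lips intact.
#'
#' @param grid A [dem_grid()] (any single-band layer).
#' @param element A [disc_element()] (or compatible offsets list).
#' @return A [dem_grid()] of the filtered values.
#' @export
#'
#' @examples
#' g <- dem_grid(matrix(c(5, 5, 0, 5, 5), 1, 5), cell_size_m = 1)
#' # a notch narrower than the element is filled
#' grayscale_closing(g, disc_element(3))$values
grayscale_dilation <- function(grid, element = disc_element(7)) {
  stopifnot(inherits(grid, "dem_grid"))
  check_element_fits(grid, element)
  grid_like(grid, morph_filter(grid$values, element, "max"))
}

#' @rdname grayscale_dilation
#' @export
grayscale_erosion <- function(grid, element = disc_element(7)) {
  stopifnot(inherits(grid, "dem_grid"))
  check_element_fits(grid, element)
  grid_like(grid, morph_filter(grid$values, element, "min"))
}

#' @rdname grayscale_dilation
#' @export
grayscale_closing <- function(grid, element = disc_element(7)) {
  grayscale_erosion(grayscale_dilation(grid, element), element)
}

check_element_fits <- function(grid, element) {
  if (element$diameter_px > max(dim(grid$values))) {
    stop("structuring element larger than the raster", call. = FALSE)
  }
  invisible(TRUE)
}
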