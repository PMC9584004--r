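# Neighbour access with edge replication: the value at (i+dr, j+dc),
# clamped to the grid, so border cells see themselves beyond the edge.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# NA neighbours fall back to the centre value so that a single nodata cell
# does not blank its whole neighbourhood; all-nodata windows stay NA
# because the centre itself is NA.
shift_fill <- function(m, dr, dc) {
  s <- shift_mat(m, dr, dc)
  bad <- is.na(s) & !is.na(m)
  s[bad] <- m[bad]
  s
}

horn_gradient <- function(grid) {
  z <- grid$values
  cs <- grid$cell_size_m
  nw <- shift_fill(z, -1, -1); n <- shift_fill(z, -1, 0); ne <- shift_fill(z, -1, 1)
  w  <- shift_fill(z,  0, -1);                            e  <- shift_fill(z,  0, 1)
  sw <- shift_fill(z,  1, -1); s <- shift_fill(z,  1, 0); se <- shift_fill(z,  1, 1)
  # row 1 is north, so +row is -y
  p <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * cs)  # dz/dx, eastward
  q <- ((nw + 2 * n + ne) - (sw + 2 * s + se)) / (8 * cs)  # dz/dy, northward
  list(p = p, q = q)
}

#' Slope of a terrain model in degrees
#'
#' Horn's 3x3 finite-difference gradient (the common GIS estimator), with
#' edge cells handled by replicating the border.
#'
#' @param dem A [dem_grid()] of elevations in metres, at least 3x3.
#' @return A [dem_grid()] of slope in degrees.
#' @export
#'
#' @examples
#' ramp <- dem_grid(outer(rep(1, 5), 0:4) * 1, cell_size_m = 1)
#' terrain_slope(ramp)$values[3, 3]  # 45 degrees on a unit-gradient plane
terrain_slope <- function(dem) {
  stopifnot(inherits(dem, "dem_grid"))
  if (any(dim(dem$values) < 3)) stop("dem must be at least 3x3", call. = FALSE)
  g <- horn_gradient(dem)
  grid_like(dem, atan(sqrt(g$p^2 + g$q^2)) * 180 / pi, layer = "slope_deg")
}

#' Aspect in compass degrees (downslope direction, clockwise from north)
#'
#' Flat cells (zero gradient) get `NA`.
#'
#' @inheritParams terrain_slope
#' @return A [dem_grid()] of aspect in `[0, 360)` degrees.
#' @export
terrain_aspect <- function(dem) {
  stopifnot(inherits(dem, "dem_grid"))
  g <- horn_gradient(dem)
  a <- atan2(-g$p, -g$q) * 180 / pi
  a <- (a + 360) %% 360
  a[g$p == 0 & g$q == 0] <- NA
  grid_like(dem, a, layer = "aspect_deg")
}

#' Terrain ruggedness index (Riley)
#'
#' Square root of the summed squared elevation differences between a cell
#' and its eight neighbours.
#'
#' @inheritParams terrain_slope
#' @return A [dem_grid()] named `tri`.
#' @export
terrain_tri <- function(dem) {
  stopifnot(inherits(dem, "dem_grid"))
  z <- dem$values
  acc <- matrix(0, nrow(z), ncol(z))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + (z - shift_fill(z, dr, dc))^2
  }
  grid_like(dem, sqrt(acc), layer = "tri")
}

#' Roughness as the standard deviation of elevation in a moving window
#'
#' The population standard deviation of elevation within a square window,
#' an alternative roughness measure to [terrain_tri()].
#'
#' @inheritParams terrain_slope
#' @param window_px Odd window side length in pixels.
#' @return A [dem_grid()] named `roughness_sd`.
#' @export
terrain_roughness_sd <- function(dem, window_px = 3) {
  stopifnot(inherits(dem, "dem_grid"), window_px %% 2 == 1, window_px >= 3)
  z <- dem$values
  h <- (window_px - 1) / 2
  s <- matrix(0, nrow(z), ncol(z))
  s2 <- matrix(0, nrow(z), ncol(z))
  n <- 0
  for (dr in -h:h) for (dc in -h:h) {
    v <- shift_fill(z, dr, dc)
    s <- s + v
    s2 <- s2 + v^2
    n <- n + 1
  }
  grid_like(dem, sqrt(pmax(s2 / n - (s / n)^2, 0)), layer = "roughness_sd")
}

#' Topographic position index
#'
#' Elevation of a cell minus the mean elevation of its neighbours within a
#' given radius (centre excluded). Positive on ridges and mounds, negative
#' in hollows.
#'
#' @inheritParams terrain_slope
#' @param radius_m Neighbourhood radius in metres (default 10).
#' @return A [dem_grid()] named `tpi`.
#' @export
terrain_tpi <- function(dem, radius_m = 10) {
  stopifnot(inherits(dem, "dem_grid"), radius_m > 0)
  z <- dem$values
  r_px <- radius_m / dem$cell_size_m
  h <- floor(r_px)
  s <- matrix(0, nrow(z), ncol(z))
  n <- 0
  for (dr in -h:h) for (dc in -h:h) {
    if (dr == 0 && dc == 0) next
    if (dr^2 + dc^2 > r_px^2) next
    s <- s + shift_fill(z, dr, dc)
    n <- n + 1
  }
  if (n == 0) stop("radius_m smaller than one cell", call. = FALSE)
  grid_like(dem, z - s / n, layer = "tpi")
}

#' Heat load index (McCune-Keon)
#'
#' Folded-aspect proxy for incident solar radiation: aspect is folded about
#' 225 degrees, `A = |180 - |aspect - 225||`, so south-west slopes score
#' highest. Three published equation variants are available; the default
#' (`equation = 3`) is the non-exponential form
#' `0.339 + 0.808 cos(L)cos(S) - 0.196 sin(L)sin(S) - 0.482 cos(A)sin(S)`
#' with latitude `L` and slope `S`.
#'
#' @inheritParams terrain_slope
#' @param latitude_deg Site latitude in degrees (required).
#' @param equation Which published equation to use: 1, 2 (exponential forms)
#'   or 3 (default).
#' @return A [dem_grid()] named `hli`.
#' @export
terrain_hli <- function(dem, latitude_deg, equation = 3) {
  stopifnot(inherits(dem, "dem_grid"))
  if (missing(latitude_deg) || is.null(latitude_deg)) {
    stop("latitude_deg is required for the heat load index", call. = FALSE)
  }
  slope <- terrain_slope(dem)$values
  aspect <- terrain_aspect(dem)$values
  aspect[is.na(aspect) & !is.na(slope)] <- 0  # flat: sin(S)=0, A irrelevant
  A <- abs(180 - abs(aspect - 225)) * pi / 180
  S <- slope * pi / 180
  L <- latitude_deg * pi / 180
  hli <- switch(as.character(equation),
    "1" = exp(-1.467 + 1.582 * cos(L) * cos(S) - 1.500 * cos(A) * sin(S) * sin(L) -
                0.262 * sin(L) * sin(S) + 0.607 * sin(A) * sin(S)),
    "2" = exp(-1.236 + 1.350 * cos(L) * cos(S) - 1.376 * cos(A) * sin(S) * sin(L) -
                0.331 * sin(L) * sin(S) + 0.294 * sin(A) * sin(S)),
    "3" = 0.339 + 0.808 * cos(L) * cos(S) - 0.196 * sin(L) * sin(S) -
      0.482 * cos(A) * sin(S),
    stop("equation must be 1, 2 or 3", call. = FALSE)
  )
  grid_like(dem, hli, layer = "hli")
}

#' Topographic wetness index
#'
#' `ln(a / tan beta)` with the specific contributing area `a` from
#' single-flow-direction (D8) accumulation (flow to the steepest downslope
#' neighbour, contour width one cell) and `tan beta` from the Horn slope,
#' floored at `min_tan_beta` to keep flat cells finite.
#'
#' @inheritParams terrain_slope
#' @param min_tan_beta Floor applied to `tan(beta)` (default 0.001).
#' @return A [dem_grid()] named `twi`.
#' @export
terrain_twi <- function(dem, min_tan_beta = 0.001) {
  stopifnot(inherits(dem, "dem_grid"), min_tan_beta > 0)
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  cs <- dem$cell_size_m
  n_cell <- nr * nc
  # steepest-descent D8 receiver of every cell (column-major linear index)
  best_drop <- matrix(-Inf, nr, nc)
  receiver <- matrix(NA_integer_, nr, nc)
  idx <- matrix(seq_len(n_cell), nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    dist <- cs * sqrt(dr^2 + dc^2)
    nb <- shift_mat(z, dr, dc)
    drop <- (z - nb) / dist
    nb_idx <- shift_mat(idx, dr, dc)
    upd <- !is.na(drop) & drop > best_drop & nb_idx != idx
    best_drop[upd] <- drop[upd]
    receiver[upd] <- nb_idx[upd]
  }
  receiver[best_drop <= 0] <- NA_integer_  # pits and flats keep their water
  acc <- rep(1, n_cell)
  acc[is.na(as.vector(z))] <- NA
  ord <- order(as.vector(z), decreasing = TRUE, na.last = NA)
  rec <- as.vector(receiver)
  for (k in ord) {
    r <- rec[k]
    if (!is.na(r)) acc[r] <- acc[r] + acc[k]
  }
  a <- acc * cs  # specific contributing area per unit contour width
  tb <- pmax(tan(terrain_slope(dem)$values * pi / 180), min_tan_beta)
  grid_like(dem, matrix(log(a / as.vector(tb)), nr, nc), layer = "twi")
}

#' Euclidean distance from every cell to the nearest feature point
#'
#' Line features should be supplied densified as vertex points.
#'
#' @param grid A [dem_grid()] providing the target geometry.
#' @param points Data frame with `x`, `y` columns in planar metres.
#' @return A [dem_grid()] of distances in metres.
#' @export
distance_grid <- function(grid, points) {
  stopifnot(inherits(grid, "dem_grid"))
  if (is.null(points) || nrow(points) == 0) {
    stop("at least one feature point is required", call. = FALSE)
  }
  cc <- grid_coords(grid)
  d2min <- matrix(Inf, nrow(grid$values), ncol(grid$values))
  for (i in seq_len(nrow(points))) {
    d2 <- outer((cc$y - points$y[i])^2, (cc$x - points$x[i])^2, "+")
    d2min <- pmin(d2min, d2)
  }
  grid_like(grid, sqrt(d2min), layer = "distance_m")
}

#' Gaussian kernel density of point features
#'
#' Isotropic Gaussian kernel with standard deviation `bandwidth_m`; the
#' raster integrates (sum times cell area) to the number of points when the
#' grid pads the points by a few bandwidths.
#'
#' @inheritParams distance_grid
#' @param bandwidth_m Kernel standard deviation in metres.
#' @return A [dem_grid()] of density per square metre.
#' @export
kernel_density_grid <- function(grid, points, bandwidth_m) {
  stopifnot(inherits(grid, "dem_grid"))
  if (is.null(points) || nrow(points) == 0) {
    stop("at least one feature point is required", call. = FALSE)
  }
  if (!is.numeric(bandwidth_m) || bandwidth_m <= 0) {
    stop("bandwidth_m must be positive", call. = FALSE)
  }
  cc <- grid_coords(grid)
  dens <- matrix(0, nrow(grid$values), ncol(grid$values))
  s2 <- bandwidth_m^2
  for (i in seq_len(nrow(points))) {
    d2 <- outer((cc$y - points$y[i])^2, (cc$x - points$x[i])^2, "+")
    dens <- dens + exp(-d2 / (2 * s2))
  }
  grid_like(grid, dens / (2 * pi * s2), layer = "kernel_density")
}

#' Assemble co-registered covariate layers into a stack
#'
#' A covariate stack is a named list of [dem_grid()] layers sharing shape
#' and georeferencing; [zonal_summaries()] consumes one.
#'
#' @param ... Named [dem_grid()] layers.
#' @return A named list of class `covariate_stack`.
#' @export
covariate_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "dem_grid")) {
    layers <- layers[[1]]
  }
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("all layers must be named", call. = FALSE)
  }
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!inherits(l, "dem_grid")) stop("layer ", nm, " is not a dem_grid", call. = FALSE)
    if (!identical(dim(l$values), dim(ref$values)) ||
        !isTRUE(all.equal(l$cell_size_m, ref$cell_size_m)) ||
        !isTRUE(all.equal(l$origin_xy, ref$origin_xy))) {
      stop("layer ", nm, " is not co-registered with the first layer", call. = FALSE)
    }
  }
  structure(layers, class = c("covariate_stack", "list"))
}

#' Standard terrain covariates in one call
#'
#' Convenience wrapper deriving slope, roughness (both variants), TPI, TWI
#' and optionally HLI from a terrain model.
#'
#' @inheritParams terrain_slope
#' @param tpi_radius_m TPI neighbourhood radius in metres.
#' @param latitude_deg Latitude for HLI; when `NULL` the HLI layer is skipped.
#' @param hli_equation Passed to [terrain_hli()].
#' @return A [covariate_stack()].
#' @export
terrain_indices <- function(dem, tpi_radius_m = 10, latitude_deg = NULL,
                            hli_equation = 3) {
  layers <- list(
    slope_deg = terrain_slope(dem),
    tri = terrain_tri(dem),
    roughness_sd = terrain_roughness_sd(dem),
    tpi = terrain_tpi(dem, tpi_radius_m),
    twi = terrain_twi(dem)
  )
  if (!is.null(latitude_deg)) {
    layers$hli <- terrain_hli(dem, latitude_deg, hli_equation)
  }
  covariate_stack(layers)
}
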