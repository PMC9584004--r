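#' Species abundances to per-unit proportions
#'
#' Converts charcoal fragment counts (historical units) or basal areas
#' (current plots) to proportions per survey unit, so the two eras are
#' comparable. Taxon columns are divided by the row total; merged
#' indistinct categories (e.g. a Larix/Picea class) are kept as their own
#' taxon. Rows with a zero total carry no information and are dropped with
#' a warning.
#'
#' @param df Tibble with one row per unit; non-taxon columns (ids,
#'   coordinates, era tags) pass through unchanged.
#' @param taxa Character vector naming the taxon columns. Defaults to all
#'   numeric columns except `id`, `unit`, `x`, `y`, `era`.
#' @return A tibble of the same shape with taxon columns as proportions
#'   summing to 1 per row.
#' @export
#'
#' @examples
#' to_proportions(tibble::tibble(id = 1, Pinus = 3, Fagus = 1))
to_proportions <- function(df, taxa = NULL) {
  df <- tibble::as_tibble(df)
  if (is.null(taxa)) {
    taxa <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                    c("id", "unit", "x", "y", "era"))
  }
  if (length(taxa) == 0) stop("no taxon columns found", call. = FALSE)
  m <- as.matrix(df[taxa])
  if (any(m < 0, na.rm = TRUE)) stop("abundances must be non-negative", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " unit(s) with zero total abundance dropped")
    df <- df[tot > 0, , drop = FALSE]
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  df[taxa] <- m / tot
  df
}

idw_weights <- function(px, py, x0, y0, power, n_neighbours, eps = 1e-9) {
  d2 <- (px - x0)^2 + (py - y0)^2
  k <- min(n_neighbours, length(d2))
  use <- order(d2)[seq_len(k)]
  d <- sqrt(d2[use])
  if (d[1] < eps) {
    w <- rep(0, k)
    w[1] <- 1
  } else {
    w <- d^(-power)
    w <- w / sum(w)
  }
  list(idx = use, w = w)
}

#' Inverse distance weighting of point values to a raster surface
#'
#' Deterministic interpolation `z(s) = sum(w_i z_i) / sum(w_i)` with
#' `w_i = d_i^-power` over the `n_neighbours` nearest sample points
#' (variable search radius). An exact interpolator: a cell coinciding with
#' a sample (distance below 1e-9 m) takes that sample's value. Because the
#' weights are a convex combination, predictions never leave the range of
#' the samples used.
#'
#' @param points Tibble with `x`, `y` and the value column.
#' @param value_col Name of the column to interpolate.
#' @param grid A [dem_grid()] giving the target geometry, or `NULL` to
#'   build one from the point bounding box.
#' @param cell_m Cell size when building the grid (default 10 m).
#' @param power Inverse-distance exponent (default 2).
#' @param n_neighbours Number of nearest points used (default 50).
#' @param pad_m Padding around the bounding box when building the grid.
#' @return A [dem_grid()] of the interpolated surface.
#' @export
idw_surface <- function(points, value_col = "value", grid = NULL,
                        cell_m = 10, power = 2, n_neighbours = 50,
                        pad_m = 0) {
  stopifnot(nrow(points) >= 1, power > 0, n_neighbours >= 1)
  if (is.null(grid)) grid <- idw_grid_for(points, cell_m, pad_m)
  z <- points[[value_col]]
  cc <- grid_coords(grid)
  out <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  for (j in seq_along(cc$x)) {
    for (i in seq_along(cc$y)) {
      ww <- idw_weights(points$x, points$y, cc$x[j], cc$y[i],
                        power, n_neighbours)
      out[i, j] <- sum(ww$w * z[ww$idx])
    }
  }
  grid_like(grid, out, layer = value_col)
}

idw_grid_for <- function(points, cell_m, pad_m = 0) {
  x0 <- floor((min(points$x) - pad_m) / cell_m) * cell_m
  y1 <- ceiling((max(points$y) + pad_m) / cell_m) * cell_m
  nc <- max(1, ceiling((max(points$x) + pad_m - x0) / cell_m))
  nr <- max(1, ceiling((y1 - (min(points$y) - pad_m)) / cell_m))
  dem_grid(matrix(NA_real_, nr, nc), cell_size_m = cell_m,
           origin_xy = c(x0, y1), layer = "idw")
}

#' Interpolate a whole composition table with shared neighbour sets
#'
#' Every taxon column is interpolated with the same nearest-neighbour sets
#' and weights (they depend only on the point geometry), which guarantees
#' that the taxon surfaces sum to 1 cell-wise whenever the input rows do.
#'
#' @param comp Proportion table from [to_proportions()] with `x`, `y`.
#' @param taxa Taxon columns (default: numeric columns except ids/coords).
#' @inheritParams idw_surface
#' @return Named list of [dem_grid()] surfaces, one per taxon.
#' @export
interpolate_composition <- function(comp, taxa = NULL, grid = NULL,
                                    cell_m = 10, power = 2,
                                    n_neighbours = 50, pad_m = 0) {
  if (is.null(taxa)) {
    taxa <- setdiff(names(comp)[vapply(comp, is.numeric, logical(1))],
                    c("id", "unit", "x", "y", "era"))
  }
  if (is.null(grid)) grid <- idw_grid_for(comp, cell_m, pad_m)
  Z <- as.matrix(comp[taxa])
  cc <- grid_coords(grid)
  mats <- lapply(taxa, function(t) matrix(NA_real_, nrow(grid$values),
                                          ncol(grid$values)))
  names(mats) <- taxa
  for (j in seq_along(cc$x)) {
    for (i in seq_along(cc$y)) {
      ww <- idw_weights(comp$x, comp$y, cc$x[j], cc$y[i], power, n_neighbours)
      vals <- drop(ww$w %*% Z[ww$idx, , drop = FALSE])
      for (t in taxa) mats[[t]][i, j] <- vals[[t]]
    }
  }
  lapply(taxa, function(t) grid_like(grid, mats[[t]], layer = t)) |>
    setNames(taxa)
}

#' Leave-one-out accuracy of the IDW interpolator
#'
#' Each sample point is predicted from the remaining points with the same
#' IDW parameters; reported are the mean error, mean absolute error,
#' root-mean-square error (all in the units of the value, proportions
#' here) and the R-squared of the predicted-versus-measured least-squares
#' fit.
#'
#' @inheritParams idw_surface
#' @return A one-row tibble with `me`, `mae`, `rmse`, `r_squared`, `n`.
#' @export
idw_accuracy <- function(points, value_col = "value", power = 2,
                         n_neighbours = 50) {
  n <- nrow(points)
  if (n < 3) stop("leave-one-out accuracy needs at least 3 points", call. = FALSE)
  z <- points[[value_col]]
  pred <- numeric(n)
  for (i in seq_len(n)) {
    ww <- idw_weights(points$x[-i], points$y[-i], points$x[i], points$y[i],
                      power, n_neighbours)
    pred[i] <- sum(ww$w * z[-i][ww$idx])
  }
  err <- pred - z
  r2 <- if (sd(pred) == 0 || sd(z) == 0) NA_real_ else cor(pred, z)^2
  tibble::tibble(
    me = mean(err), mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
    r_squared = r2, n = n
  )
}

#' Cell-wise composition change between eras
#'
#' Current minus historical proportion surface; values lie in `[-1, 1]`,
#' positive where a taxon expanded.
#'
#' @param current,historical Co-registered proportion [dem_grid()]s.
#' @return A [dem_grid()] of differences.
#' @export
change_map <- function(current, historical) {
  stopifnot(inherits(current, "dem_grid"), inherits(historical, "dem_grid"))
  if (!identical(dim(current$values), dim(historical$values))) {
    stop("rasters are not co-registered", call. = FALSE)
  }
  grid_like(current, current$values - historical$values,
            layer = paste0(current$layer, "_change"))
}

#' Brillouin diversity index
#'
#' `H = (ln N! - sum ln n_i!) / N` for a fully censused collection of
#' integer abundances, evaluated through log-gamma. Zero-abundance classes
#' contribute nothing.
#'
#' @param abundances Non-negative integer abundances, total at least 1.
#' @param tol Tolerance for accepting near-integer input.
#' @return The index (0 for a single species).
#' @export
#'
#' @examples
#' brillouin(c(2, 2))  # (ln 24 - 2 ln 2) / 4
brillouin <- function(abundances, tol = 1e-9) {
  if (any(abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (any(abs(abundances - round(abundances)) > tol)) {
    stop("abundances must be integers; see brillouin_basal_area() for basal areas",
         call. = FALSE)
  }
  n <- round(abundances)
  N <- sum(n)
  if (N < 1) stop("total abundance must be at least 1", call. = FALSE)
  (lgamma(N + 1) - sum(lgamma(n + 1))) / N
}

#' Brillouin index from basal areas
#'
#' The index requires counts; basal area in m2/ha is scaled (default
#' times 10, i.e. one "individual" per 0.1 m2/ha) and rounded to the
#' nearest integer before the formula is applied. This discretisation is
#' an interpretation, not part of the index, and the scale is
#' configurable.
#'
#' @param basal_area Non-negative basal areas (m2/ha).
#' @param scale Multiplier applied before rounding (default 10).
#' @return The Brillouin index of the discretised abundances.
#' @export
brillouin_basal_area <- function(basal_area, scale = 10) {
  if (any(basal_area < 0)) stop("basal areas must be non-negative", call. = FALSE)
  brillouin(round(basal_area * scale))
}
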