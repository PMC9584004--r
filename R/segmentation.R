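#' Seed placement for region growing
#'
#' Seeds are the local minima of the (closed) slope raster that fall below
#' a flatness quantile, thinned greedily in order of increasing value so
#' that no two seeds lie closer than `min_distance_m`. On a hearth
#' landscape the flat platform interiors are the deepest minima of the
#' morphologically closed slope, so each platform attracts one seed.
#'
#' @param grid A [dem_grid()], typically the closed slope.
#' @param min_distance_m Minimum planar distance between seeds (default 10).
#' @param flatness_quantile Keep only minima at or below this quantile of
#'   the raster values (default 0.3).
#' @return A tibble with `row`, `col`, `x`, `y`, `value`, ordered as the
#'   seeds were accepted. Empty (with a warning) when no cell qualifies.
#' @export
select_seeds <- function(grid, min_distance_m = 10, flatness_quantile = 0.3) {
  stopifnot(inherits(grid, "dem_grid"))
  v <- grid$values
  is_min <- !is.na(v)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_min <- is_min & (v <= shift_fill(v, dr, dc))
  }
  cutoff <- quantile(v, flatness_quantile, na.rm = TRUE, names = FALSE)
  cand <- which(is_min & v <= cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    warning("no cell below the flatness quantile; returning no seeds")
    return(tibble::tibble(row = integer(), col = integer(),
                          x = numeric(), y = numeric(), value = numeric()))
  }
  vals <- v[cand]
  ord <- order(vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  cs <- grid$cell_size_m
  min_d2 <- (min_distance_m / cs)^2
  keep <- integer(0)
  kr <- numeric(0)
  kc <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (length(keep) == 0 || all((kr - r)^2 + (kc - c)^2 >= min_d2)) {
      keep <- c(keep, i)
      kr <- c(kr, r)
      kc <- c(kc, c)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cc <- grid_coords(grid)
  tibble::tibble(
    row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
    x = cc$x[cand[, 2]], y = cc$y[cand[, 1]],
    value = vals[keep]
  )
}

#' Seeded region growing segmentation
#'
#' Priority-queue growth from seed cells over one or more feature layers:
#' the unassigned 4-neighbour cell with the smallest Euclidean feature
#' distance to the adjoining region's running mean is attached first; a
#' region stops when no frontier cell is within `similarity_threshold` or
#' when it reaches `max_area_m2`. Ties are broken by (row, col), so the
#' labelling is deterministic. With several layers each is standardised to
#' zero mean and unit variance before distances are taken.
#'
#' @param features A [dem_grid()] or a [covariate_stack()] / named list of
#'   co-registered grids to grow over (default use: the closed slope alone).
#' @param seeds Tibble from [select_seeds()] or any data frame with `row`
#'   and `col` columns (1-based).
#' @param similarity_threshold Positive growth threshold in feature units
#'   (standardised units when multiple layers are given).
#' @param max_area_m2 Per-region area cap; the default 340 m2 is twice the
#'   largest platform the detector is expected to meet.
#' @return A [dem_grid()] of integer labels, 0 = unassigned, class also
#'   `label_grid`.
#' @export
region_growing <- function(features, seeds, similarity_threshold,
                           max_area_m2 = 340) {
  if (inherits(features, "dem_grid")) features <- list(feature = features)
  stopifnot(length(features) >= 1)
  ref <- features[[1]]
  if (is.null(seeds) || nrow(seeds) == 0) stop("seeds must be non-empty", call. = FALSE)
  if (!is.numeric(similarity_threshold) || similarity_threshold <= 0) {
    stop("similarity_threshold must be > 0", call. = FALSE)
  }
  mats <- lapply(features, function(g) g$values)
  if (length(mats) > 1) {
    mats <- lapply(mats, function(m) {
      s <- sd(m, na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      (m - mean(m, na.rm = TRUE)) / s
    })
  }
  max_cells <- max(1L, as.integer(floor(max_area_m2 / ref$cell_size_m^2)))
  labels <- srg_cpp(unname(mats), cbind(seeds$row, seeds$col),
                    similarity_threshold, max_cells)
  out <- grid_like(ref, labels, layer = "labels")
  class(out) <- c("label_grid", class(out))
  out
}

#' Relabel a label grid so labels are contiguous positive integers
#' @param labels A label [dem_grid()].
#' @return The same grid with labels renumbered 1..k in first-appearance
#'   order (column-major).
#' @export
compact_labels <- function(labels) {
  v <- labels$values
  u <- unique(as.vector(v))
  u <- sort(u[u > 0])
  map <- integer(max(u, 0))
  map[u] <- seq_along(u)
  pos <- v > 0
  v[pos] <- map[v[pos]]
  out <- grid_like(labels, v, layer = "labels")
  class(out) <- unique(c("label_grid", class(out)))
  out
}

#' Jaccard overlap between a labelled region and a truth mask
#'
#' @param labels A label [dem_grid()].
#' @param label Which region label to compare.
#' @param mask Logical matrix of the truth footprint (same shape).
#' @return Intersection over union in `[0, 1]`.
#' @export
jaccard_index <- function(labels, label, mask) {
  a <- labels$values == label
  a[is.na(a)] <- FALSE
  inter <- sum(a & mask)
  uni <- sum(a | mask)
  if (uni == 0) return(NA_real_)
  inter / uni
}
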