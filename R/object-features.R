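#' Gini coefficient of a set of non-negative values
#'
#' Mean absolute difference between all pairs, normalised by twice the
#' mean: `G = sum_ij |x_i - x_j| / (2 n^2 xbar)` (population form). The
#' sample-corrected variant divides by `n (n - 1)` instead of `n^2`.
#'
#' @param values Non-negative numeric vector, `n >= 1`.
#' @param unbiased Use the `n (n - 1)` denominator instead of `n^2`.
#' @return Gini coefficient in `[0, 1)`; 0 when the mean is 0.
#' @export
#'
#' @examples
#' gini(c(0, 0, 0, 1))  # 0.75
gini <- function(values, unbiased = FALSE) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("need at least one value", call. = FALSE)
  if (any(values < 0)) stop("Gini is defined for non-negative values", call. = FALSE)
  tot <- sum(values)
  if (tot == 0) return(0)
  x <- sort(values)
  g <- sum((2 * seq_len(n) - n - 1) * x) / (n * tot)
  if (unbiased) {
    if (n < 2) stop("unbiased Gini needs n >= 2", call. = FALSE)
    g <- g * n / (n - 1)
  }
  g
}

zonal_stat_names <- c("min", "max", "range", "sum", "mean", "variance", "sd",
                      "gini", "p05", "p25", "p50", "p75", "p95")

zonal_stats_vec <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(setNames(rep(NA_real_, 13), zonal_stat_names))
  }
  q <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
  n <- length(x)
  v <- sum((x - mean(x))^2) / n  # population variance
  g <- if (all(x >= 0)) gini(x) else NA_real_
  c(min = min(x), max = max(x), range = max(x) - min(x), sum = sum(x),
    mean = mean(x), variance = v, sd = sqrt(v), gini = g,
    p05 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5])
}

#' Per-object summary statistics over covariate layers
#'
#' For every labelled object and every layer of the stack: minimum,
#' maximum, range, sum, mean, variance (population), standard deviation,
#' Gini coefficient, and the 0.05/0.25/0.50/0.75/0.95 percentiles (linear
#' interpolation). Columns follow the `<layer>_<stat>` convention. The
#' Gini coefficient needs non-negative values and is `NA` on layers that
#' go negative (e.g. the position index); objects whose layer values are
#' all nodata get `NA` statistics.
#'
#' @param labels A label [dem_grid()] from [region_growing()].
#' @param stack A [covariate_stack()] (or single [dem_grid()]) co-registered
#'   with the labels.
#' @return A tibble, one row per object: `label`, `n_cells`, then the 13
#'   statistics per layer.
#' @export
zonal_summaries <- function(labels, stack) {
  stopifnot(inherits(labels, "dem_grid"))
  if (inherits(stack, "dem_grid")) {
    stack <- stats::setNames(list(stack), stack$layer)
  }
  lv <- as.vector(labels$values)
  keep <- !is.na(lv) & lv > 0
  ids <- sort(unique(lv[keep]))
  out <- tibble::tibble(
    label = ids,
    n_cells = as.vector(table(factor(lv[keep], levels = ids)))
  )
  for (nm in names(stack)) {
    if (!identical(dim(stack[[nm]]$values), dim(labels$values))) {
      stop("layer ", nm, " is not co-registered with the labels", call. = FALSE)
    }
    vals <- as.vector(stack[[nm]]$values)[keep]
    stats_by <- vapply(split(vals, factor(lv[keep], levels = ids)),
                       zonal_stats_vec, numeric(13))
    st <- t(stats_by)
    colnames(st) <- paste(nm, zonal_stat_names, sep = "_")
    out <- dplyr::bind_cols(out, tibble::as_tibble(st))
  }
  out
}

#' Geometry of labelled objects
#'
#' Area (pixel count times cell area), perimeter (count of exposed pixel
#' edges times cell size), centroid, perimeter/area ratio, circularity
#' `4 pi A / P^2`, and the perimeter/area ratio of the circle with the
#' same area, `2 sqrt(pi / A)` — the analytic reference a compact hearth
#' platform is compared against.
#'
#' @param labels A label [dem_grid()].
#' @return A tibble, one row per object: `label`, `n_cells`, `centroid_x`,
#'   `centroid_y`, `area_m2`, `perimeter_m`, `pa_ratio`, `circularity`,
#'   `circle_pa_ratio`.
#' @export
#'
#' @examples
#' m <- matrix(0L, 12, 12); m[2:11, 2:11] <- 1L
#' g <- dem_grid(m * 1, cell_size_m = 1)
#' shape_metrics(g)  # 10x10 square: area 100, perimeter 40
shape_metrics <- function(labels) {
  stopifnot(inherits(labels, "dem_grid"))
  v <- labels$values
  v[is.na(v)] <- 0
  ids <- sort(unique(as.vector(v)))
  ids <- ids[ids > 0]
  if (length(ids) == 0) stop("no labelled objects", call. = FALSE)
  cs <- labels$cell_size_m
  edge_counts <- numeric(max(ids))
  pad_shift <- function(m, dr, dc) {
    # like shift_mat but outside cells read 0 (background), not replicated
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs_ <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs_ - dc] <- m[rs, cs_]
    out
  }
  for (k in 1:4) {
    dr <- c(-1, 1, 0, 0)[k]
    dc <- c(0, 0, -1, 1)[k]
    nb <- pad_shift(v, dr, dc)
    exposed <- v > 0 & nb != v
    tt <- tabulate(v[exposed], nbins = max(ids))
    edge_counts <- edge_counts + tt
  }
  lvec <- as.vector(v)
  keep <- lvec > 0
  f <- factor(lvec[keep], levels = ids)
  cc <- grid_coords(labels)
  d <- dim(v)
  xs <- rep(cc$x, each = d[1])[keep]
  ys <- rep(cc$y, times = d[2])[keep]
  n_cells <- as.vector(table(f))
  area <- n_cells * cs^2
  perim <- edge_counts[ids] * cs
  tibble::tibble(
    label = ids,
    n_cells = n_cells,
    centroid_x = as.vector(tapply(xs, f, mean)),
    centroid_y = as.vector(tapply(ys, f, mean)),
    area_m2 = area,
    perimeter_m = perim,
    pa_ratio = perim / area,
    circularity = 4 * pi * area / perim^2,
    circle_pa_ratio = circle_pa_ratio(area)
  )
}

#' Perimeter/area ratio of a circle of given area
#'
#' For a circle, `P / A = 2 sqrt(pi / A)` in reciprocal metres.
#'
#' @param area_m2 Positive area in square metres.
#' @return The ratio in 1/m.
#' @export
#'
#' @examples
#' circle_pa_ratio(63.2)  # about 0.45
circle_pa_ratio <- function(area_m2) {
  stopifnot(all(area_m2 > 0))
  2 * sqrt(pi / area_m2)
}

#' Outer boundary ring of a labelled object
#'
#' Walks the exposed pixel edges with the object interior kept on the left
#' and returns the longest closed ring (holes are dropped), as planar
#' vertex coordinates suitable for [write_geojson_polygons()].
#'
#' @param labels A label [dem_grid()].
#' @param label The object label to trace.
#' @return A two-column matrix of ring vertices (x, y), closed.
#' @export
object_outline <- function(labels, label) {
  v <- labels$values
  v[is.na(v)] <- 0
  mask <- v == label
  if (!any(mask)) stop("label not present", call. = FALSE)
  cs <- labels$cell_size_m
  ox <- labels$origin_xy[1]
  oy <- labels$origin_xy[2]
  cells <- which(mask, arr.ind = TRUE)
  # directed boundary edges between lattice corners, interior on the left
  edges <- list()
  nr <- nrow(v); nc <- ncol(v)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1]; c <- cells[i, 2]
    tl <- c(c - 1, r - 1); tr <- c(c, r - 1); br <- c(c, r); bl <- c(c - 1, r)
    if (!inside(r - 1, c)) edges[[length(edges) + 1]] <- c(tr, tl)
    if (!inside(r + 1, c)) edges[[length(edges) + 1]] <- c(bl, br)
    if (!inside(r, c - 1)) edges[[length(edges) + 1]] <- c(tl, bl)
    if (!inside(r, c + 1)) edges[[length(edges) + 1]] <- c(br, tr)
  }
  E <- do.call(rbind, edges)  # columns: x0, y0, x1, y1 in lattice units
  key <- function(p) paste(p[1], p[2])
  from <- apply(E[, 1:2, drop = FALSE], 1, key)
  used <- rep(FALSE, nrow(E))
  out_by_start <- split(seq_len(nrow(E)), from)
  rings <- list()
  for (start in seq_len(nrow(E))) {
    if (used[start]) next
    ring <- list(E[start, 1:2])
    cur <- start
    used[cur] <- TRUE
    repeat {
      endp <- E[cur, 3:4]
      ring[[length(ring) + 1]] <- endp
      cand <- out_by_start[[key(endp)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      if (length(cand) > 1) {
        # ambiguous corner (diagonal touch): take the leftmost turn
        dir <- E[cur, 3:4] - E[cur, 1:2]
        turn <- vapply(cand, function(j) {
          d2 <- E[j, 3:4] - E[j, 1:2]
          atan2(dir[1] * d2[2] - dir[2] * d2[1], sum(dir * d2))
        }, numeric(1))
        cand <- cand[which.max(turn)]
      }
      cur <- cand[1]
      used[cur] <- TRUE
    }
    rings[[length(rings) + 1]] <- do.call(rbind, ring)
  }
  ring <- rings[[which.max(vapply(rings, nrow, integer(1)))]]
  # lattice corners to planar coordinates (row axis points south)
  cbind(x = ox + ring[, 1] * cs, y = oy - ring[, 2] * cs)
}
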