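#' Density of detected hearths per hectare
#'
#' Count divided by a reference area. For a landscape survey the natural
#' denominator is the forested area rather than the whole watershed (a
#' charcoal hearth is a forest feature); both are worth reporting when they
#' differ.
#'
#' @param count Non-negative integer number of hearths.
#' @param reference_area_ha Positive reference area in hectares.
#' @return A list with `density_per_ha` (raw) and `density_rounded`
#'   (one decimal).
#' @export
#'
#' @examples
#' rch_density(744, 1600)  # 0.465 raw, 0.5 rounded
rch_density <- function(count, reference_area_ha) {
  if (!is.numeric(reference_area_ha) || reference_area_ha <= 0) {
    stop("reference_area_ha must be positive", call. = FALSE)
  }
  if (count < 0) stop("count must be non-negative", call. = FALSE)
  d <- count / reference_area_ha
  list(density_per_ha = d, density_rounded = round(d, 1))
}

#' Build a hearth inventory from detections and terrain layers
#'
#' Joins per-object geometry with elevation and slope sampled at the
#' centroid cell and distances to roads and buildings, giving the table
#' the geometric summaries are computed from.
#'
#' @param shapes Tibble from [shape_metrics()] (detected hearths only).
#' @param dem The elevation [dem_grid()].
#' @param slope Optional slope grid (derived from `dem` when `NULL`).
#' @param roads,buildings Optional point tables (`x`, `y`) of linear/built
#'   features; distances are `NA` when absent.
#' @return A tibble, one row per hearth: centroid, `area_m2`,
#'   `perimeter_m`, `pa_ratio`, `elevation_m`, `slope_deg`, `dist_road_m`,
#'   `dist_building_m`.
#' @export
rch_inventory <- function(shapes, dem, slope = NULL, roads = NULL,
                          buildings = NULL) {
  stopifnot(inherits(dem, "dem_grid"))
  if (is.null(slope)) slope <- terrain_slope(dem)
  rc <- xy_to_cell(dem, shapes$centroid_x, shapes$centroid_y)
  lin <- cbind(rc[, "row"], rc[, "col"])
  dist_to <- function(pts) {
    if (is.null(pts) || nrow(pts) == 0) return(rep(NA_real_, nrow(shapes)))
    vapply(seq_len(nrow(shapes)), function(i) {
      min(sqrt((pts$x - shapes$centroid_x[i])^2 +
                 (pts$y - shapes$centroid_y[i])^2))
    }, numeric(1))
  }
  tibble::tibble(
    id = shapes$label,
    x = shapes$centroid_x, y = shapes$centroid_y,
    area_m2 = shapes$area_m2, perimeter_m = shapes$perimeter_m,
    pa_ratio = shapes$pa_ratio,
    elevation_m = dem$values[lin],
    slope_deg = slope$values[lin],
    dist_road_m = dist_to(roads),
    dist_building_m = dist_to(buildings)
  )
}

#' Geometric and spatial summary of a hearth inventory
#'
#' Mean/min/max of area and perimeter/area ratio, an area histogram, and
#' Pearson correlations of area with elevation and with slope (two-sided p
#' from the t approximation).
#'
#' @param inventory A tibble from [rch_inventory()] (needs `area_m2`,
#'   `pa_ratio`; correlations also need `elevation_m`, `slope_deg`).
#' @param breaks Passed to [graphics::hist()] binning (computed without
#'   plotting).
#' @return A list with tibbles `summary` (one row per variable),
#'   `correlations` (one row per pair) and `area_histogram` (bin mids and
#'   counts).
#' @export
geometry_report <- function(inventory, breaks = "Sturges") {
  stopifnot(all(c("area_m2", "pa_ratio") %in% names(inventory)))
  summarise_var <- function(v, nm) {
    tibble::tibble(variable = nm, n = sum(!is.na(v)),
                   mean = mean(v, na.rm = TRUE),
                   min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
  }
  smry <- dplyr::bind_rows(
    summarise_var(inventory$area_m2, "area_m2"),
    summarise_var(inventory$pa_ratio, "pa_ratio")
  )
  cor_row <- function(x, y, nm) {
    ok <- complete.cases(x, y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(pair = nm, n = sum(ok),
                            r = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(x[ok], y[ok])
    tibble::tibble(pair = nm, n = sum(ok), r = unname(ct$estimate),
                   p_value = ct$p.value)
  }
  cors <- dplyr::bind_rows(
    if ("elevation_m" %in% names(inventory)) {
      cor_row(inventory$area_m2, inventory$elevation_m, "area_vs_elevation")
    },
    if ("slope_deg" %in% names(inventory)) {
      cor_row(inventory$area_m2, inventory$slope_deg, "area_vs_slope")
    }
  )
  h <- graphics::hist(inventory$area_m2, breaks = breaks, plot = FALSE)
  list(
    summary = smry,
    correlations = cors,
    area_histogram = tibble::tibble(mid_m2 = h$mids, count = h$counts)
  )
}
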