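#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange. The header stores the lower-left corner;
#' [dem_grid()] georeferencing uses the upper-left corner, and the
#' conversion is handled here. Values are written row by row from the
#' northernmost row, `NA` as the `NODATA_value` sentinel.
#'
#' @param grid A [dem_grid()].
#' @param path File path (`.asc`).
#' @param nodata Sentinel written for `NA` cells.
#' @param digits Significant digits used when formatting values.
#' @return `write_esri_ascii()` returns `path` invisibly;
#'   `read_esri_ascii()` returns a [dem_grid()].
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(grid, "dem_grid"))
  d <- dim(grid$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", grid$origin_xy[1]),
    sprintf("yllcorner %.10g", grid$origin_xy[2] - d[1] * grid$cell_size_m),
    sprintf("cellsize %.10g", grid$cell_size_m),
    sprintf("NODATA_value %.10g", nodata)
  )
  v <- grid$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @param layer Layer name given to the grid read back in.
#' @export
read_esri_ascii <- function(path, layer = "elevation") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  dem_grid(
    m, cell_size_m = hdr$cellsize,
    origin_xy = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
    layer = layer
  )
}

#' Write point features with attributes as GeoJSON
#'
#' @param df Data frame with `x` and `y` columns (planar metres); all other
#'   columns become feature properties.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  stopifnot(all(c("x", "y") %in% names(df)))
  props <- df[setdiff(names(df), c("x", "y"))]
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df$x[i], df$y[i])),
      properties = as.list(props[i, , drop = FALSE])
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_geojson_points
#' @export
read_geojson_points <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- purrr::map(fc$features, function(f) {
    co <- unlist(f$geometry$coordinates)
    props <- f$properties
    props[vapply(props, is.null, logical(1))] <- NA
    tibble::as_tibble(c(list(x = co[1], y = co[2]), props))
  })
  dplyr::bind_rows(rows)
}

#' Write polygon outlines as GeoJSON
#'
#' @param polys Named list of rings; each ring is a two-column matrix of
#'   planar vertex coordinates (closed automatically).
#' @param properties Optional data frame with one row per polygon.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    ring <- polys[[i]]
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2]))
    props <- if (is.null(properties)) {
      list(id = i)
    } else {
      as.list(properties[i, , drop = FALSE])
    }
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(coords)),
      properties = props
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
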