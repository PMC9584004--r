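#' Describe a synthetic hillslope scenario
#'
#' Bundles the parameters of the synthetic-landscape generator: a planar
#' hillslope ramp with band-limited correlated noise, into which flat
#' elliptical charcoal-hearth platforms (bounded by 1-2 m wide lips) and
#' confuser landforms (gullies, boulders, terracettes) are carved. The
#' defaults mirror the survey conditions the detector is meant for:
#' 0.5 m cells, platforms of 20-170 m2, 212 platforms against 453
#' confusers.
#'
#' @param extent_m Width and height of the landscape in metres.
#' @param cell_size_m Raster resolution (default 0.5 m).
#' @param base_slope_deg Mean hillslope gradient in degrees.
#' @param relief_amplitude_m Standard deviation of the correlated noise
#'   added to the ramp (0 gives a perfect plane).
#' @param noise_bandwidth_m Gaussian smoothing bandwidth of the noise.
#' @param n_platforms Number of hearth platforms to embed.
#' @param platform_area_range_m2 Min/max platform area.
#' @param lip_width_range_m Min/max lip annulus width.
#' @param n_confusers Number of confuser landforms.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A list of class `terrain_scenario`.
#' @export
terrain_scenario <- function(extent_m = c(600, 600), cell_size_m = 0.5,
                             base_slope_deg = 25, relief_amplitude_m = 0.35,
                             noise_bandwidth_m = 4, n_platforms = 212,
                             platform_area_range_m2 = c(20, 170),
                             lip_width_range_m = c(1, 2),
                             n_confusers = 453, seed = 42) {
  stopifnot(
    length(extent_m) == 2, all(extent_m > 0),
    cell_size_m > 0, base_slope_deg >= 0, base_slope_deg < 90,
    relief_amplitude_m >= 0, noise_bandwidth_m > 0,
    n_platforms >= 0, n_confusers >= 0,
    length(platform_area_range_m2) == 2,
    platform_area_range_m2[1] > 0,
    diff(platform_area_range_m2) >= 0,
    length(lip_width_range_m) == 2, lip_width_range_m[1] > 0,
    diff(lip_width_range_m) >= 0
  )
  structure(
    list(
      extent_m = extent_m, cell_size_m = cell_size_m,
      base_slope_deg = base_slope_deg,
      relief_amplitude_m = relief_amplitude_m,
      noise_bandwidth_m = noise_bandwidth_m,
      n_platforms = n_platforms,
      platform_area_range_m2 = platform_area_range_m2,
      lip_width_range_m = lip_width_range_m,
      n_confusers = n_confusers, seed = seed
    ),
    class = "terrain_scenario"
  )
}

#' @export
print.terrain_scenario <- function(x, ...) {
  cat(sprintf(
    "<terrain_scenario> %g x %g m at %g m, slope %g deg, %d platforms (%g-%g m2), %d confusers, seed %d\n",
    x$extent_m[1], x$extent_m[2], x$cell_size_m, x$base_slope_deg,
    x$n_platforms, x$platform_area_range_m2[1], x$platform_area_range_m2[2],
    x$n_confusers, x$seed
  ))
  invisible(x)
}

gauss_smooth <- function(m, sigma_px) {
  h <- max(1L, ceiling(3 * sigma_px))
  off <- -h:h
  k <- exp(-off^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  tmp <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(off)) tmp <- tmp + k[i] * shift_mat(m, off[i], 0)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(off)) out <- out + k[i] * shift_mat(tmp, 0, off[i])
  out
}

# non-overlap placement by rejection: centres further apart than the sum of
# the exclusion radii plus a 1 m buffer
place_objects <- function(radii, extent, margin, placed_x = numeric(0),
                          placed_y = numeric(0), placed_r = numeric(0),
                          max_retry = 400, what = "object") {
  xs <- ys <- numeric(length(radii))
  for (i in seq_along(radii)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      cx <- runif(1, margin + radii[i], extent[1] - margin - radii[i])
      cy <- runif(1, margin + radii[i], extent[2] - margin - radii[i])
      if (length(placed_x) == 0 ||
          all(sqrt((placed_x - cx)^2 + (placed_y - cy)^2) >
                placed_r + radii[i] + 1)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("could only place %d of %d %ss without overlap",
                   i - 1, length(radii), what), call. = FALSE)
    }
    xs[i] <- cx
    ys[i] <- cy
    placed_x <- c(placed_x, cx)
    placed_y <- c(placed_y, cy)
    placed_r <- c(placed_r, radii[i])
  }
  list(x = xs, y = ys,
       all_x = placed_x, all_y = placed_y, all_r = placed_r)
}

#' Generate a synthetic terrain model with ground-truthed hearth platforms
#'
#' Builds the hillslope described by a [terrain_scenario()]: a planar ramp
#' of the requested gradient plus Gaussian-smoothed correlated noise.
#' Each platform is an ellipse levelled at the elevation of its centre and
#' blended back into the slope through a lip annulus by a linear ramp, so
#' the platform interior is flat and the lip locally steeper than the
#' surrounding hillslope. Confusers are landforms that are locally steep
#' but not flat-centred: gullies (tapered trenches whose floor follows the
#' slope), boulders (convex bumps) and terracettes (narrow elongated
#' benches). Deterministic given the scenario seed.
#'
#' @param scenario A [terrain_scenario()].
#' @return A list with `dem` (a [dem_grid()]), `truth` (tibble of platform
#'   ground truth: centroid, area, axes, orientation, lip width, and the
#'   footprint cell indices as a list column) and `confusers` (tibble of
#'   confuser type, centre and size).
#' @export
#'
#' @examples
#' sc <- terrain_scenario(extent_m = c(60, 60), n_platforms = 2,
#'                        n_confusers = 2, seed = 7)
#' out <- generate_dtm(sc)
#' out$truth
generate_dtm <- function(scenario) {
  stopifnot(inherits(scenario, "terrain_scenario"))
  set.seed(scenario$seed)
  cs <- scenario$cell_size_m
  nc <- round(scenario$extent_m[1] / cs)
  nr <- round(scenario$extent_m[2] / cs)
  dem <- dem_grid(matrix(0, nr, nc), cell_size_m = cs,
                  origin_xy = c(0, scenario$extent_m[2]))
  cc <- grid_coords(dem)
  # ramp dipping south: z rises with northing at the requested gradient
  z <- matrix(rep(tan(scenario$base_slope_deg * pi / 180) * cc$y, nc), nr, nc)
  noise <- matrix(0, nr, nc)
  if (scenario$relief_amplitude_m > 0) {
    noise <- gauss_smooth(matrix(rnorm(nr * nc), nr, nc),
                          scenario$noise_bandwidth_m / cs)
    noise <- noise / sd(noise) * scenario$relief_amplitude_m
  }
  terrain_only <- z + noise

  # -- platforms ------------------------------------------------------
  n_p <- scenario$n_platforms
  areas <- runif(n_p, scenario$platform_area_range_m2[1],
                 scenario$platform_area_range_m2[2])
  ratio <- runif(n_p, 0.75, 1)
  a_ax <- sqrt(areas / (pi * ratio))
  b_ax <- a_ax * ratio
  theta <- runif(n_p, 0, pi)
  lip_w <- runif(n_p, scenario$lip_width_range_m[1],
                 scenario$lip_width_range_m[2])
  margin <- 3
  pl <- if (n_p > 0) {
    place_objects(a_ax + lip_w, scenario$extent_m, margin, what = "platform")
  } else {
    list(x = numeric(0), y = numeric(0), all_x = numeric(0),
         all_y = numeric(0), all_r = numeric(0))
  }

  zmod <- terrain_only
  footprints <- vector("list", n_p)
  tilt_deg <- runif(n_p, 0, 1.5)  # platforms weather: a slight residual tilt
  tilt_dir <- runif(n_p, 0, 2 * pi)
  for (i in seq_len(n_p)) {
    win <- platform_window(dem, pl$x[i], pl$y[i], a_ax[i] + lip_w[i] + cs)
    dx <- outer(rep(1, length(win$rows)), cc$x[win$cols] - pl$x[i])
    dy <- outer(cc$y[win$rows] - pl$y[i], rep(1, length(win$cols)))
    u <- dx * cos(theta[i]) + dy * sin(theta[i])
    v <- -dx * sin(theta[i]) + dy * cos(theta[i])
    rho <- sqrt((u / a_ax[i])^2 + (v / b_ax[i])^2)
    r_eff <- sqrt(a_ax[i] * b_ax[i])
    rho_out <- 1 + lip_w[i] / r_eff
    z_plat <- terrain_only[win$rows[which.min(abs(cc$y[win$rows] - pl$y[i]))],
                           win$cols[which.min(abs(cc$x[win$cols] - pl$x[i]))]]
    sub <- zmod[win$rows, win$cols]
    t_blend <- pmin(pmax((rho - 1) / (rho_out - 1), 0), 1)
    plat_z <- z_plat +
      tan(tilt_deg[i] * pi / 180) *
        (dx * cos(tilt_dir[i]) + dy * sin(tilt_dir[i])) +
      0.12 * noise[win$rows, win$cols]  # micro-relief; interior stays < 3 deg
    new_sub <- (1 - t_blend) * plat_z + t_blend * sub
    zmod[win$rows, win$cols] <- new_sub
    fp <- which(rho <= 1, arr.ind = TRUE)
    footprints[[i]] <- as.integer(
      (win$cols[fp[, 2]] - 1L) * nr + win$rows[fp[, 1]]
    )
  }

  # -- confusers ------------------------------------------------------
  n_c <- scenario$n_confusers
  types <- rep(c("gully", "boulder", "terracette"), length.out = n_c)
  conf_len <- runif(n_c, 8, 20)    # gully / terracette length
  conf_wid <- runif(n_c, 1.2, 3)   # trench / bench width
  conf_ht <- runif(n_c, 0.8, 2.2)  # depth or boulder height
  conf_rad <- ifelse(types == "boulder", runif(n_c, 1.5, 3.5), conf_len / 2)
  co <- if (n_c > 0) {
    place_objects(conf_rad + 1, scenario$extent_m, margin,
                  placed_x = pl$all_x, placed_y = pl$all_y,
                  placed_r = pl$all_r, what = "confuser")
  } else {
    list(x = numeric(0), y = numeric(0))
  }
  for (i in seq_len(n_c)) {
    win <- platform_window(dem, co$x[i], co$y[i], conf_rad[i] + 2)
    dx <- outer(rep(1, length(win$rows)), cc$x[win$cols] - co$x[i])
    dy <- outer(cc$y[win$rows] - co$y[i], rep(1, length(win$cols)))
    sub <- zmod[win$rows, win$cols]
    if (types[i] == "boulder") {
      s2 <- (conf_rad[i] / 2)^2
      sub <- sub + conf_ht[i] * exp(-(dx^2 + dy^2) / (2 * s2))
    } else {
      ang <- runif(1, 0, pi)
      along <- dx * cos(ang) + dy * sin(ang)
      across <- -dx * sin(ang) + dy * cos(ang)
      taper <- exp(-(along / (conf_len[i] / 2))^4)
      prof <- exp(-(across / (conf_wid[i] / 2))^2) * taper
      if (types[i] == "gully") {
        sub <- sub - conf_ht[i] * prof  # trench floor keeps the ramp dip
      } else {
        # terracette: pull the band towards its centre-line elevation
        centre_z <- terrain_only[win$rows, win$cols] -
          dy * tan(scenario$base_slope_deg * pi / 180)
        sub <- sub + prof * 0.8 * (centre_z - sub)
      }
    }
    zmod[win$rows, win$cols] <- sub
  }

  dem <- grid_like(dem, zmod)
  truth <- tibble::tibble(
    id = seq_len(n_p),
    x = pl$x, y = pl$y,
    area_m2 = areas[seq_len(n_p)],
    axis_a_m = a_ax[seq_len(n_p)], axis_b_m = b_ax[seq_len(n_p)],
    theta = theta[seq_len(n_p)], lip_width_m = lip_w[seq_len(n_p)],
    footprint = footprints
  )
  confusers <- tibble::tibble(
    id = seq_len(n_c), type = types[seq_len(n_c)],
    x = co$x, y = co$y, size_m = conf_rad[seq_len(n_c)]
  )
  list(dem = dem, truth = truth, confusers = confusers, scenario = scenario)
}

platform_window <- function(dem, cx, cy, radius) {
  d <- dim(dem$values)
  rc <- xy_to_cell(dem, cx, cy)
  h <- ceiling(radius / dem$cell_size_m)
  list(
    rows = max(1, rc[1, "row"] - h):min(d[1], rc[1, "row"] + h),
    cols = max(1, rc[1, "col"] - h):min(d[2], rc[1, "col"] + h)
  )
}

#' Logical footprint mask of one ground-truth platform
#' @param dem The generated [dem_grid()].
#' @param truth The truth tibble from [generate_dtm()].
#' @param id Platform id.
#' @return Logical matrix of the platform footprint.
#' @export
truth_mask <- function(dem, truth, id) {
  m <- matrix(FALSE, nrow(dem$values), ncol(dem$values))
  m[truth$footprint[[which(truth$id == id)]]] <- TRUE
  m
}

#' Default charcoal taxon probabilities
#'
#' Pinus-dominated historical composition with a merged indistinct
#' Larix/Picea class, mirroring the taxon groups an anthracological survey
#' distinguishes under the microscope.
#' @return Named probability vector summing to 1.
#' @export
default_taxon_probs <- function() {
  c(Pinus = 0.62, Fagus = 0.15, Picea = 0.08, LarixPicea = 0.13, other = 0.02)
}

#' Simulate charcoal fragment counts per hearth
#'
#' Each hearth yields a uniform number of identifiable fragments between
#' `frags_per_rch[1]` and `frags_per_rch[2]`, assigned to taxa by a
#' multinomial draw. An optional smooth spatial trend tilts the log-odds
#' of one taxon linearly along x, producing the spatially structured
#' composition a change map should recover.
#'
#' @param truth Tibble with hearth `id`, `x`, `y` (e.g. from
#'   [generate_dtm()], or any point table).
#' @param taxon_probs Named probabilities summing to 1 (default
#'   [default_taxon_probs()]).
#' @param frags_per_rch Integer min/max fragments per hearth (default 2-6).
#' @param seed Integer seed.
#' @param spatial_trend Optional `list(taxon =, amplitude =)`: log-odds of
#'   that taxon shifted by `± amplitude` from the west to the east edge.
#' @return A tibble: `id`, `x`, `y`, one count column per taxon, and
#'   `era = "historical"`.
#' @export
generate_charcoal_samples <- function(truth,
                                      taxon_probs = default_taxon_probs(),
                                      frags_per_rch = c(2, 6), seed = 1,
                                      spatial_trend = NULL) {
  if (any(taxon_probs < 0)) stop("taxon probabilities must be non-negative", call. = FALSE)
  if (abs(sum(taxon_probs) - 1) > 1e-9) {
    stop("taxon probabilities must sum to 1", call. = FALSE)
  }
  if (frags_per_rch[1] < 1) stop("minimum fragments per hearth is 1", call. = FALSE)
  set.seed(seed)
  n <- nrow(truth)
  sizes <- seq(frags_per_rch[1], frags_per_rch[2])
  n_frag <- sizes[sample.int(length(sizes), n, replace = TRUE)]
  taxa <- names(taxon_probs)
  counts <- matrix(0L, n, length(taxa), dimnames = list(NULL, taxa))
  if (!is.null(spatial_trend)) {
    xr <- range(truth$x)
    u <- if (diff(xr) > 0) (truth$x - mean(xr)) / (diff(xr) / 2) else rep(0, n)
  }
  for (i in seq_len(n)) {
    p <- taxon_probs
    if (!is.null(spatial_trend)) {
      lo <- log(pmax(p, 1e-12))
      lo[spatial_trend$taxon] <- lo[spatial_trend$taxon] +
        spatial_trend$amplitude * u[i]
      p <- exp(lo) / sum(exp(lo))
    }
    counts[i, ] <- as.integer(stats::rmultinom(1, n_frag[i], p))
  }
  dplyr::bind_cols(
    tibble::tibble(id = truth$id, x = truth$x, y = truth$y),
    tibble::as_tibble(counts),
    tibble::tibble(era = "historical")
  )
}

table1_env_names <- function() {
  c("Rch_d", "Rch_k", "movCo", "road", "build", "elev", "slope", "roug",
    "hli", "Twet", "Tpi", "Tri", "pH", "Corg", "C_N")
}

table1_response_names <- function() {
  c("tph", "ba", "dbh", "tcd", "piun", "pisy", "lade", "fasy", "piab",
    "otbr", "brill")
}

default_plot_coefficients <- function(env_names = table1_env_names(),
                                      response_names = table1_response_names()) {
  B <- matrix(0, length(env_names), length(response_names),
              dimnames = list(env_names, response_names))
  # gradient 1: the elevation/heat belt every descriptor responds to -
  # dense mountain pine up high, larger beech/larch stands and higher
  # diversity below (response pattern s across tph, ba, dbh, tcd, piun,
  # pisy, lade, fasy, piab, otbr, brill)
  s <- c(0.5, -0.7, -0.8, -0.6, 1.0, -0.8, 0.6, -0.9, 0.5, -0.6, -0.9)
  # gradient 2: hearth influence - dense young stands near old charcoal
  # platforms; decorrelated from the elevation pattern so the two
  # gradients span separate ordination axes
  t <- c(0.9, 0.4, -0.2, 0.7, 0.6, 0.3, -0.5, 0.2, -0.4, -0.3, 0.4)
  t <- t - sum(t * s) / sum(s * s) * s
  B["elev", ] <- s
  B["hli", ] <- 0.2 * c(-0.3, 0.4, 0.6, -0.2, -0.3, 0.2, 0.8, -0.4, -0.5,
                        0.1, 0.2)
  B["Rch_k", ] <- t
  # fertility: beech, Scots pine and diversity on milder soils
  B["C_N", "fasy"] <- -0.25
  B["C_N", "brill"] <- -0.2
  B["pH", "pisy"] <- 0.25
  B["Twet", "piab"] <- 0.3
  B
}

#' Parameter set for synthetic forest plot generation
#'
#' Environmental variables are generated on two smooth spatial gradients
#' plus variable-specific noise; the forest descriptors respond linearly
#' (on the standardised scale) through a known coefficient matrix, plus
#' Gaussian noise. The default coefficient matrix loads the descriptors on
#' an elevation/heat gradient and a hearth-influence gradient.
#'
#' @param env_names,response_names Variable codes (defaults: the 15
#'   environmental and 11 forest-structure codes used throughout).
#' @param coefficients `length(env_names) x length(response_names)` matrix
#'   of standardised linear effects; `NULL` for the default.
#' @param noise_sd Residual standard deviation of the standardised
#'   responses (scalar or per response).
#' @param extent_m Spatial extent the plots are scattered over.
#' @return A list of class `plot_env_model`.
#' @export
forest_env_model <- function(env_names = table1_env_names(),
                             response_names = table1_response_names(),
                             coefficients = NULL, noise_sd = 0.42,
                             extent_m = c(4000, 4000)) {
  if (is.null(coefficients)) {
    coefficients <- if (identical(env_names, table1_env_names()) &&
                        identical(response_names, table1_response_names())) {
      default_plot_coefficients()
    } else {
      matrix(0, length(env_names), length(response_names),
             dimnames = list(env_names, response_names))
    }
  }
  coefficients <- as.matrix(coefficients)
  if (!all(dim(coefficients) == c(length(env_names), length(response_names)))) {
    stop("coefficient matrix must be n_env x n_response", call. = FALSE)
  }
  noise_sd <- rep_len(noise_sd, length(response_names))
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative", call. = FALSE)
  structure(
    list(env_names = env_names, response_names = response_names,
         coefficients = coefficients, noise_sd = noise_sd,
         extent_m = extent_m),
    class = "plot_env_model"
  )
}

#' Simulate forest inventory plots with known environmental responses
#'
#' Scatters `n_plots` plot centres over the model extent, generates the
#' environmental matrix on two smooth spatial gradients, and produces the
#' forest structure/composition descriptors as known linear responses plus
#' noise. The true coefficient matrix is returned for recovery tests.
#'
#' @param n_plots Number of plots (at least 10; 267 matches a one-plot-
#'   per-6-ha inventory of a 1600 ha forest).
#' @param env_model A [forest_env_model()].
#' @param seed Integer seed.
#' @return List with tibbles `plots` (responses + coordinates) and `env`
#'   (predictors + coordinates), and the model (`coefficients`,
#'   `noise_sd`).
#' @export
generate_forest_plots <- function(n_plots = 267,
                                  env_model = forest_env_model(),
                                  seed = 1) {
  stopifnot(inherits(env_model, "plot_env_model"))
  if (n_plots < 10) stop("need at least 10 plots", call. = FALSE)
  set.seed(seed)
  ex <- env_model$extent_m
  x <- runif(n_plots, 0, ex[1])
  y <- runif(n_plots, 0, ex[2])
  g1 <- (x - ex[1] / 2) / ex[1]
  g2 <- (y - ex[2] / 2) / ex[2]
  p <- length(env_model$env_names)
  w1 <- seq(-1, 1, length.out = p)
  w2 <- rev(seq(-0.8, 0.8, length.out = p))
  E <- vapply(seq_len(p), function(j) {
    w1[j] * g1 + w2[j] * g2 + rnorm(n_plots, sd = 0.35)
  }, numeric(n_plots))
  colnames(E) <- env_model$env_names
  if (any(apply(E, 2, sd) == 0)) {
    stop("degenerate environmental model: zero-variance predictor", call. = FALSE)
  }
  Ez <- scale(E)
  q <- length(env_model$response_names)
  Yz <- Ez %*% env_model$coefficients +
    matrix(rnorm(n_plots * q), n_plots, q) %*% diag(env_model$noise_sd, q)
  colnames(Yz) <- env_model$response_names
  # rescale to plausible field units (affine, so standardised analyses are
  # unaffected)
  units <- plot_units()[env_model$response_names]
  Y <- Yz
  for (j in seq_len(q)) {
    u <- units[[j]] %||% c(0, 1)
    Y[, j] <- pmax(Yz[, j] * u[2] + u[1], 0)
  }
  env <- dplyr::bind_cols(tibble::tibble(plot = seq_len(n_plots), x = x, y = y),
                          tibble::as_tibble(E))
  plots <- dplyr::bind_cols(tibble::tibble(plot = seq_len(n_plots), x = x, y = y),
                            tibble::as_tibble(Y))
  list(plots = plots, env = env,
       coefficients = env_model$coefficients, noise_sd = env_model$noise_sd)
}

plot_units <- function() {
  list(
    tph = c(650, 250), ba = c(28, 9), dbh = c(22, 6), tcd = c(55, 18),
    piun = c(12, 6), pisy = c(4, 2.5), lade = c(6, 3.5), fasy = c(3, 2.5),
    piab = c(1.5, 1.2), otbr = c(1, 0.8), brill = c(0.9, 0.35)
  )
}
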