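test_that("slope reproduces analytic planes and is transpose-consistent", {
  flat <- dem_grid(matrix(7, 6, 6), 1)
  expect_true(all(terrain_slope(flat)$values == 0))

  ramp1 <- dem_grid(outer(rep(1, 7), 0:6) * 1, 1)
  expect_equal(terrain_slope(ramp1)$values[3:5, 3:5],
               matrix(45, 3, 3))

  ramp05 <- dem_grid(outer(rep(1, 7), 0:6) * 0.5, 1)
  got <- terrain_slope(ramp05)$values[4, 4]
  expect_equal(got, atan(0.5) * 180 / pi, tolerance = 1e-10)
  # central-difference oracle at the same cell
  z <- ramp05$values
  p_cd <- (z[4, 5] - z[4, 3]) / 2
  q_cd <- (z[3, 4] - z[5, 4]) / 2
  expect_equal(got, atan(sqrt(p_cd^2 + q_cd^2)) * 180 / pi, tolerance = 1e-10)

  g <- random_grid(12, 9, seed = 3)
  gt <- dem_grid(t(g$values), 1)
  expect_equal(terrain_slope(gt)$values, t(terrain_slope(g)$values))
})

test_that("ruggedness and position indices match direct evaluation", {
  flat <- dem_grid(matrix(2.5, 5, 5), 1)
  expect_true(all(terrain_tri(flat)$values == 0))
  expect_true(all(abs(terrain_tpi(flat, 2)$values) < 1e-12))

  m <- matrix(0, 3, 3)
  m[2, 2] <- 1
  expect_equal(terrain_tri(dem_grid(m, 1))$values[2, 2], sqrt(8))

  # TPI averages to about zero over a periodic surface
  nx <- 40
  per <- dem_grid(outer(sin(2 * pi * (1:nx) / nx),
                        cos(2 * pi * (1:nx) / nx)), 1)
  tpi <- terrain_tpi(per, 4)$values
  expect_lt(abs(mean(tpi[5:36, 5:36])), 0.02)
})

test_that("heat load index follows the folded-aspect equation", {
  flat <- dem_grid(matrix(5, 5, 5), 1)
  expect_equal(terrain_hli(flat, 45.67)$values[3, 3],
               0.339 + 0.808 * cos(45.67 * pi / 180), tolerance = 1e-12)
  expect_error(terrain_hli(flat), "latitude")
  # exponential variants stay positive and respond to slope
  ramp <- dem_grid(outer(rep(1, 7), 0:6) * 0.3, 1)
  for (eq in 1:2) {
    expect_true(all(terrain_hli(ramp, 45, equation = eq)$values > 0))
  }
})

test_that("wetness index accumulates flow downslope on a plane", {
  # south-dipping plane: row 1 is the crest
  n <- 11
  dem <- dem_grid(matrix(rep(seq(10, 0, length.out = n), n), n, n), 1,
                  origin_xy = c(0, n))
  twi <- terrain_twi(dem)$values
  # interior column: wetness grows monotonically downslope
  col <- twi[2:(n - 1), 6]
  expect_true(all(diff(col) > 0))
  # crest cell: unit contributing area, a = cell size
  tanb <- tan(terrain_slope(dem)$values[2, 6] * pi / 180)
  expect_equal(twi[2, 6], log(2 * 1 / tanb), tolerance = 1e-10)
})

test_that("distance rasters are exact and satisfy the triangle inequality", {
  g <- dem_grid(matrix(0, 10, 10), 1, origin_xy = c(0, 10))
  d <- distance_grid(g, tibble::tibble(x = 0.5, y = 9.5))
  expect_equal(d$values[1, 1], 0)
  expect_equal(d$values[xy_to_cell(g, 3.5, 5.5)], 5)  # 3-4-5 triangle
  expect_error(distance_grid(g, tibble::tibble(x = numeric(0), y = numeric(0))),
               "at least one")

  set.seed(11)
  pts <- tibble::tibble(x = runif(5, 0, 10), y = runif(5, 0, 10))
  dm <- distance_grid(g, pts)$values
  cc <- grid_coords(g)
  for (rep in 1:25) {
    i1 <- sample(10, 1); j1 <- sample(10, 1)
    i2 <- sample(10, 1); j2 <- sample(10, 1)
    sep <- sqrt((cc$x[j1] - cc$x[j2])^2 + (cc$y[i1] - cc$y[i2])^2)
    expect_lte(abs(dm[i1, j1] - dm[i2, j2]), sep + 1e-9)
  }
})

test_that("kernel density integrates to the point count", {
  g <- dem_grid(matrix(0, 100, 100), 1, origin_xy = c(0, 100))
  set.seed(4)
  pts <- tibble::tibble(x = runif(10, 30, 70), y = runif(10, 30, 70))
  kd <- kernel_density_grid(g, pts, bandwidth_m = 5)
  expect_equal(sum(kd$values) * 1, 10, tolerance = 0.01)
  expect_error(kernel_density_grid(g, pts, bandwidth_m = -1), "positive")
})

test_that("covariate stacks enforce co-registration", {
  a <- dem_grid(matrix(0, 4, 4), 1)
  b <- dem_grid(matrix(1, 4, 4), 1)
  expect_silent(covariate_stack(ele = a, other = b))
  wrong <- dem_grid(matrix(1, 5, 4), 1)
  expect_error(covariate_stack(ele = a, other = wrong), "co-registered")
})
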