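test_that("gini matches hand-computed and analytic cases", {
  expect_equal(gini(c(3, 3, 3)), 0)
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini(rep(0, 5)), 0)  # zero mean defined as 0
  expect_error(gini(c(-1, 2)), "non-negative")
  # exponential samples converge to the analytic value 1/2
  set.seed(9)
  expect_equal(gini(rexp(20000)), 0.5, tolerance = 0.015)
  # scale invariance and the sample-corrected variant
  set.seed(10)
  x <- runif(50)
  expect_equal(gini(3.7 * x), gini(x))
  expect_equal(gini(x, unbiased = TRUE), gini(x) * 50 / 49)
})

test_that("zonal statistics agree with direct computation", {
  lab <- dem_grid(matrix(c(1, 1, 1, 2, 2, 2, 2, 0, 0), 3, 3), 1)
  class(lab) <- c("label_grid", class(lab))
  layer <- dem_grid(matrix(c(1, 2, 3, 7, 7, 7, 7, 9, 9), 3, 3), 1,
                    layer = "v")
  z <- zonal_summaries(lab, layer)
  r1 <- z[z$label == 1, ]
  expect_equal(r1$v_sum, 6)
  expect_equal(r1$v_mean, 2)
  expect_equal(r1$v_variance, 2 / 3)
  expect_equal(r1$v_sd, sqrt(2 / 3))
  r2 <- z[z$label == 2, ]
  expect_equal(r2$v_min, 7)
  expect_equal(r2$v_max, 7)
  expect_equal(r2$v_range, 0)
  expect_equal(r2$v_variance, 0)
  expect_equal(r2$v_gini, 0)
  # percentiles interpolate linearly: p50 of four values 7,7,9,9 is 8
  lab2 <- dem_grid(matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3, 3), 1)
  lay2 <- dem_grid(matrix(c(7, 9, 7, 9, 0, 0, 0, 0, 0), 3, 3), 1, layer = "v")
  expect_equal(zonal_summaries(lab2, lay2)$v_p50, 8)
})

test_that("zonal statistics are ordered and permutation-invariant", {
  set.seed(12)
  for (rep in 1:5) {
    x <- runif(sample(5:40, 1), 0, 100)
    s <- charcoalscape:::zonal_stats_vec(x)
    expect_true(all(diff(s[c("min", "p05", "p25", "p50", "p75", "p95",
                             "max")]) >= -1e-12))
    expect_equal(charcoalscape:::zonal_stats_vec(sample(x)), s)
  }
})

test_that("shape metrics match hand geometry", {
  one <- dem_grid(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3), 0.5)
  s1 <- shape_metrics(one)
  expect_equal(s1$area_m2, 0.25)
  expect_equal(s1$perimeter_m, 2)
  expect_equal(s1$pa_ratio, 8)

  sq <- matrix(0, 12, 12)
  sq[2:11, 2:11] <- 1
  s2 <- shape_metrics(dem_grid(sq, 1))
  expect_equal(s2$area_m2, 100)
  expect_equal(s2$perimeter_m, 40)
  expect_equal(s2$circularity, 4 * pi * 100 / 1600)

  expect_equal(round(circle_pa_ratio(63.2), 2), 0.45)
})

test_that("object outlines close and enclose the pixel area", {
  sq <- matrix(0, 12, 12)
  sq[3:9, 4:8] <- 1
  g <- dem_grid(sq, 1, origin_xy = c(0, 12))
  ring <- object_outline(g, 1)
  expect_equal(ring[1, ], ring[nrow(ring), ])
  expect_equal(ring_area(ring), 7 * 5)
})
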