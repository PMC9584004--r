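test_that("seed thinning respects the minimum distance", {
  const <- dem_grid(matrix(3, 20, 20), 1, origin_xy = c(0, 20))
  seeds <- select_seeds(const, min_distance_m = 5, flatness_quantile = 0.5)
  expect_gt(nrow(seeds), 1)
  d <- as.matrix(dist(cbind(seeds$x, seeds$y)))
  expect_true(all(d[upper.tri(d)] >= 5))

  one <- select_seeds(const, min_distance_m = 100, flatness_quantile = 0.5)
  expect_equal(nrow(one), 1)
})

test_that("a single platform attracts exactly one interior seed", {
  sim <- generate_dtm(one_platform_scenario(seed = 41))
  closed <- grayscale_closing(terrain_slope(sim$dem), disc_element(7))
  seeds <- select_seeds(closed, min_distance_m = 10, flatness_quantile = 0.1)
  m <- truth_mask(sim$dem, sim$truth, 1)
  inside <- m[cbind(seeds$row, seeds$col)]
  expect_equal(sum(inside), 1)
})

test_that("region growing recovers homogeneous zones exactly", {
  z <- matrix(0, 12, 15)
  z[, 8:15] <- 100
  g <- dem_grid(z, 1)
  seeds <- tibble::tibble(row = c(6, 6), col = c(3, 12))
  lab <- region_growing(g, seeds, similarity_threshold = 10,
                        max_area_m2 = 1e6)
  expect_equal(lab$values == 1, z == 0)
  expect_equal(lab$values == 2, z == 100)

  # one seed, constant raster, no cap: everything joins one region
  const <- dem_grid(matrix(1, 8, 8), 1)
  all_one <- region_growing(const, tibble::tibble(row = 4, col = 4), 0.5,
                            max_area_m2 = 1e6)
  expect_true(all(all_one$values == 1))

  expect_error(region_growing(const, tibble::tibble(row = 1, col = 1), 0),
               "similarity_threshold")
  expect_error(region_growing(const, tibble::tibble(row = integer(0),
                                                    col = integer(0)), 1),
               "seeds")
})

test_that("regions are 4-connected, disjoint and capped in area", {
  g <- random_grid(30, 30, seed = 55)
  seeds <- tibble::tibble(row = c(5, 25, 15), col = c(5, 25, 20))
  lab <- region_growing(g, seeds, similarity_threshold = 30,
                        max_area_m2 = 50)  # 50 cells at 1 m
  counts <- table(lab$values[lab$values > 0])
  expect_true(all(counts <= 50))
  # connectivity: every labelled cell has a 4-neighbour with the same label
  v <- lab$values
  for (id in as.integer(names(counts))) {
    if (counts[[as.character(id)]] == 1) next
    cells <- which(v == id, arr.ind = TRUE)
    for (k in seq_len(nrow(cells))) {
      r <- cells[k, 1]; c <- cells[k, 2]
      nb <- c(
        if (r > 1) v[r - 1, c], if (r < nrow(v)) v[r + 1, c],
        if (c > 1) v[r, c - 1], if (c < ncol(v)) v[r, c + 1]
      )
      expect_true(any(nb == id))
    }
  }
})

test_that("segmentation is deterministic", {
  g <- random_grid(25, 25, seed = 77)
  seeds <- tibble::tibble(row = c(3, 20), col = c(4, 21))
  a <- region_growing(g, seeds, 10)
  b <- region_growing(g, seeds, 10)
  expect_identical(a$values, b$values)
})

test_that("a platform region overlaps its truth footprint strongly", {
  sim <- generate_dtm(one_platform_scenario(seed = 61))
  closed <- grayscale_closing(terrain_slope(sim$dem), disc_element(7))
  seeds <- select_seeds(closed, 10, 0.1)
  lab <- region_growing(closed, seeds, 5)
  expect_gte(max(platform_jaccards(sim, lab)), 0.7)
})
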