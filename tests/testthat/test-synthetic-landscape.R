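test_that("a noise-free scenario without platforms is a perfect ramp", {
  sc <- terrain_scenario(extent_m = c(40, 40), base_slope_deg = 20,
                         relief_amplitude_m = 0, n_platforms = 0,
                         n_confusers = 0, seed = 1)
  sim <- generate_dtm(sc)
  sl <- terrain_slope(sim$dem)$values
  interior <- sl[3:77, 3:77]
  expect_true(all(abs(interior - 20) < 1e-6))
})

test_that("platform interiors are flat and lips steeper than the hillslope", {
  sim <- generate_dtm(one_platform_scenario(area_m2 = 63, slope_deg = 25,
                                            seed = 83))
  sl <- terrain_slope(sim$dem)$values
  m <- truth_mask(sim$dem, sim$truth, 1)
  # erode the footprint so the Horn stencil never touches the lip
  interior <- which(m, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(interior)), function(k) {
    r <- interior[k, 1]; c <- interior[k, 2]
    all(m[max(1, r - 2):min(nrow(m), r + 2),
          max(1, c - 2):min(ncol(m), c + 2)])
  }, logical(1))
  inner <- interior[keep, , drop = FALSE]
  expect_gt(nrow(inner), 0)
  expect_lt(max(sl[inner]), 3)

  # lip annulus: cells just outside the footprint, within the lip width
  tr <- sim$truth
  cc <- grid_coords(sim$dem)
  xs <- matrix(cc$x, nrow(m), ncol(m), byrow = TRUE)
  ys <- matrix(cc$y, nrow(m), ncol(m))
  u <- (xs - tr$x) * cos(tr$theta) + (ys - tr$y) * sin(tr$theta)
  v <- -(xs - tr$x) * sin(tr$theta) + (ys - tr$y) * cos(tr$theta)
  rho <- sqrt((u / tr$axis_a_m)^2 + (v / tr$axis_b_m)^2)
  r_eff <- sqrt(tr$axis_a_m * tr$axis_b_m)
  lip <- rho > 1.1 & rho < 1 + 0.9 * tr$lip_width_m / r_eff
  expect_gt(quantile(sl[lip], 0.9), 25)
})

test_that("footprint discretisation matches the nominal area within 15%", {
  sim <- generate_dtm(terrain_scenario(extent_m = c(120, 120),
                                       n_platforms = 8, n_confusers = 0,
                                       seed = 89))
  cell2 <- sim$dem$cell_size_m^2
  for (i in sim$truth$id) {
    px_area <- length(sim$truth$footprint[[i]]) * cell2
    expect_lt(abs(px_area - sim$truth$area_m2[i]) / sim$truth$area_m2[i], 0.15)
  }
})

test_that("generation is bit-identical under a fixed seed", {
  sc <- terrain_scenario(extent_m = c(60, 60), n_platforms = 3,
                         n_confusers = 3, seed = 97)
  a <- generate_dtm(sc)
  b <- generate_dtm(sc)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$truth$x, b$truth$x)
  expect_identical(a$confusers$x, b$confusers$x)
})

test_that("impossible packings fail loudly with a placement count", {
  sc <- terrain_scenario(extent_m = c(30, 30), n_platforms = 40,
                         n_confusers = 0, seed = 3)
  expect_error(generate_dtm(sc), "could only place")
})

test_that("charcoal draws respect fragment bounds and degenerate probs", {
  pts <- tibble::tibble(id = 1:50, x = runif(50), y = runif(50))
  tab <- generate_charcoal_samples(pts, c(A = 1.0), seed = 5)
  expect_true(all(tab$A >= 2 & tab$A <= 6))
  expect_true(all(to_proportions(tab, "A")$A == 1))

  probs <- default_taxon_probs()
  tab2 <- generate_charcoal_samples(pts, probs, frags_per_rch = c(2, 6),
                                    seed = 6)
  totals <- rowSums(tab2[names(probs)])
  expect_true(all(totals >= 2 & totals <= 6))

  expect_error(generate_charcoal_samples(pts, c(A = 0.7, B = 0.2)), "sum to 1")
  expect_error(generate_charcoal_samples(pts, c(A = 1.2, B = -0.2)),
               "non-negative")
  expect_error(
    generate_charcoal_samples(pts, c(A = 1), frags_per_rch = c(0, 3)),
    "minimum"
  )
})

test_that("pooled proportions obey the law of large numbers", {
  set.seed(7)
  pts <- tibble::tibble(id = 1:2000, x = runif(2000), y = runif(2000))
  probs <- default_taxon_probs()
  tab <- generate_charcoal_samples(pts, probs, frags_per_rch = c(5, 5),
                                   seed = 8)
  pooled <- colSums(tab[names(probs)]) / 10000
  expect_true(all(abs(pooled - probs) < 0.02))
})

test_that("forest plots have the survey dimensions and known coefficients", {
  fp <- generate_forest_plots(267, seed = 11)
  expect_equal(dim(fp$env[table1_env_names()]), c(267, 15))
  expect_equal(dim(fp$plots[table1_response_names()]), c(267, 11))
  expect_equal(dim(fp$coefficients), c(15, 11))
  expect_error(generate_forest_plots(5), "at least 10")
})

test_that("a noise-free single-gradient model is fully explained by RDA", {
  em <- forest_env_model(env_names = "elev", response_names = "ba",
                         coefficients = matrix(1), noise_sd = 0)
  fp <- generate_forest_plots(50, em, seed = 13)
  fit <- rda_fit(as.matrix(fp$plots["ba"]), as.matrix(fp$env["elev"]))
  expect_equal(fit$proportion_pct[1], 100, tolerance = 1e-6)
})
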