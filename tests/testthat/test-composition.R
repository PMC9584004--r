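test_that("abundances convert to row-normalised proportions", {
  p <- to_proportions(tibble::tibble(id = 1, Pinus = 3, Fagus = 1))
  expect_equal(unlist(p[c("Pinus", "Fagus")], use.names = FALSE),
               c(0.75, 0.25))
  ba <- to_proportions(tibble::tibble(id = 1, a = 10, b = 10, d = 0))
  expect_equal(unlist(ba[c("a", "b", "d")], use.names = FALSE),
               c(0.5, 0.5, 0))
  expect_warning(
    out <- to_proportions(tibble::tibble(id = 1:2, a = c(1, 0), b = c(1, 0))),
    "zero total"
  )
  expect_equal(nrow(out), 1)
  expect_error(to_proportions(tibble::tibble(id = 1, a = -1, b = 2)),
               "non-negative")
})

test_that("IDW is an exact, bounded interpolator with power weighting", {
  pts <- tibble::tibble(x = c(0, 4), y = c(0, 0), value = c(0, 1))
  # prediction at a sample point returns the sample
  g0 <- dem_grid(matrix(NA_real_, 1, 1), 1, origin_xy = c(-0.5, 0.5))
  expect_equal(idw_surface(pts, grid = g0)$values[1, 1], 0)
  # midpoint of two equidistant points is their mean
  gm <- dem_grid(matrix(NA_real_, 1, 1), 1, origin_xy = c(1.5, 0.5))
  expect_equal(idw_surface(pts, grid = gm)$values[1, 1], 0.5)
  # hand-evaluated weights: values 10, 40 at distances 1, 2, power 2
  pts2 <- tibble::tibble(x = c(0, 0), y = c(1, 2), value = c(10, 40))
  gh <- dem_grid(matrix(NA_real_, 1, 1), 1, origin_xy = c(-0.5, 0.5))
  expect_equal(idw_surface(pts2, grid = gh)$values[1, 1], 16)
  # never extrapolates beyond the sample range
  set.seed(19)
  pts3 <- tibble::tibble(x = runif(30, 0, 100), y = runif(30, 0, 100),
                         value = runif(30))
  s <- idw_surface(pts3, cell_m = 10)
  expect_true(all(s$values >= min(pts3$value) - 1e-12))
  expect_true(all(s$values <= max(pts3$value) + 1e-12))
})

test_that("leave-one-out accuracy summarises errors correctly", {
  const <- tibble::tibble(x = c(0, 1, 2, 5), y = c(0, 1, 0, 3),
                          value = rep(0.4, 4))
  acc <- idw_accuracy(const)
  expect_equal(acc$me, 0)
  expect_equal(acc$mae, 0)
  expect_equal(acc$rmse, 0)
  expect_error(idw_accuracy(const[1:2, ]), "at least 3")
  # MAE <= RMSE on any input
  set.seed(23)
  for (rep in 1:5) {
    pts <- tibble::tibble(x = runif(20), y = runif(20), value = runif(20))
    a <- idw_accuracy(pts, n_neighbours = 5)
    expect_lte(a$mae, a$rmse + 1e-12)
  }
})

test_that("composition surfaces close to 1 with shared neighbour sets", {
  set.seed(29)
  n <- 40
  comp <- to_proportions(tibble::tibble(
    id = 1:n, x = runif(n, 0, 200), y = runif(n, 0, 200),
    a = rpois(n, 4) + 1, b = rpois(n, 2), d = rpois(n, 1)
  ))
  surf <- interpolate_composition(comp, c("a", "b", "d"), cell_m = 20,
                                  n_neighbours = 10)
  total <- surf$a$values + surf$b$values + surf$d$values
  expect_true(all(abs(total - 1) < 1e-6))
})

test_that("change maps subtract eras cell by cell", {
  a <- dem_grid(matrix(1, 3, 3), 1)
  b <- dem_grid(matrix(0.25, 3, 3), 1)
  expect_true(all(change_map(a, a)$values == 0))
  expect_true(all(change_map(a, b)$values == 0.75))
  expect_error(change_map(a, dem_grid(matrix(0, 2, 2), 1)), "co-registered")
})

test_that("Brillouin index matches factorial evaluation and evenness", {
  expect_equal(brillouin(c(7)), 0)
  expect_equal(brillouin(c(2, 2)), (log(24) - 2 * log(2)) / 4)
  expect_error(brillouin(c(1.5, 2)), "integers")
  expect_error(brillouin(c(0, 0)), "at least 1")
  # most even composition maximises H for fixed N (brute force, 3 classes)
  compositions <- function(N, k) {
    if (k == 1) return(matrix(N, 1, 1))
    do.call(rbind, lapply(0:N, function(i) {
      cbind(i, compositions(N - i, k - 1))
    }))
  }
  for (N in c(6, 9, 12)) {
    cm <- compositions(N, 3)
    H <- apply(cm, 1, brillouin)
    best <- cm[which.max(H), ]
    expect_lte(max(best) - min(best), 1)
  }
  # Brillouin is bounded by the Shannon entropy of the same proportions
  set.seed(31)
  for (rep in 1:10) {
    n <- rpois(4, 8) + 1
    shannon <- -sum((n / sum(n)) * log(n / sum(n)))
    expect_lte(brillouin(n), shannon + 1e-12)
  }
  # basal areas are discretised at 0.1 m2/ha per individual by default
  expect_equal(brillouin_basal_area(c(1.0, 1.0)), brillouin(c(10, 10)))
})

test_that("pooled charcoal proportions recover the taxon probabilities", {
  set.seed(37)
  pts <- tibble::tibble(id = 1:125, x = runif(125, 0, 500),
                        y = runif(125, 0, 500))
  probs <- default_taxon_probs()
  tab <- generate_charcoal_samples(pts, probs, seed = 38)
  counts <- colSums(tab[names(probs)])
  N <- sum(counts)
  pooled <- counts / N
  se <- sqrt(probs * (1 - probs) / N)
  expect_true(all(abs(pooled - probs) <= 3 * se + 1e-12))
})
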