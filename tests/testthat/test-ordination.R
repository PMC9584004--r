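test_that("noise-free responses are fully explained by their predictors", {
  set.seed(41)
  X <- matrix(rnorm(60), 30, 2)
  B <- matrix(c(1, -0.5, 0.3, 0.7, 0.2, -1), 2, 3)
  fit <- rda_fit(X %*% B, X)
  expect_equal(fit$constrained_variance, fit$total_variance, tolerance = 1e-10)
  expect_equal(sum(fit$proportion_pct), 100, tolerance = 1e-8)
})

test_that("responses orthogonal to the predictors yield null eigenvalues", {
  set.seed(43)
  X <- matrix(rnorm(50), 25, 2)
  Y <- matrix(rnorm(75), 25, 3)
  Xc <- scale(X, scale = FALSE)
  resid <- qr.resid(qr(Xc), scale(Y, scale = FALSE))
  fit <- rda_fit(resid, X, standardise_y = FALSE)
  expect_lt(max(fit$eigenvalues), 1e-12)
})

test_that("eigenvalues match a brute-force projection oracle and vegan", {
  set.seed(47)
  Y <- matrix(rnorm(60), 20, 3)
  X <- matrix(rnorm(40), 20, 2)
  fit <- rda_fit(Y, X, standardise_y = FALSE, standardise_x = FALSE)
  # oracle: explicit hat matrix, then a full eigendecomposition
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  ev <- eigen(crossprod(H %*% Yc) / (nrow(Y) - 1), symmetric = TRUE)$values
  expect_lt(max(abs(fit$eigenvalues - ev[1:2])), 1e-8)
  vfit <- vegan::rda(Y ~ X)
  expect_lt(max(abs(fit$eigenvalues - unname(vfit$CCA$eig))), 1e-8)
})

test_that("constraining on the responses themselves reduces to PCA", {
  set.seed(53)
  Y <- matrix(rnorm(80), 20, 4)
  fit <- rda_fit(Y, Y)
  pca_var <- prcomp(Y, scale. = TRUE)$sdev^2
  expect_equal(fit$eigenvalues, pca_var, tolerance = 1e-10)
  expect_lte(fit$constrained_variance, fit$total_variance + 1e-12)
})

test_that("degenerate predictor matrices are rejected with names", {
  set.seed(59)
  Y <- matrix(rnorm(30), 10, 3)
  X <- cbind(a = rnorm(10), b = 1:10)
  X2 <- cbind(X, c = X[, "a"] * 2)
  expect_error(rda_fit(Y, X2), "collinear.*c")
  expect_error(rda_fit(Y, cbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance")
  expect_error(rda_fit(Y[1:3, ], X[1:3, ]), "more rows")
})

test_that("the permutation test is exact-bounded and order-invariant", {
  set.seed(61)
  X <- matrix(rnorm(60), 30, 2)
  Y <- X %*% matrix(c(1, 0.4, -0.6, 1, 0.3, 0.3), 2, 3)
  fit <- rda_permutation_test(Y, X, n_perm = 199, seed = 7)
  expect_equal(fit$p_value, 1 / 200)

  ord <- sample(30)
  fit2 <- rda_permutation_test(Y[ord, ], X[ord, ], n_perm = 199, seed = 7)
  expect_equal(fit2$p_value, fit$p_value)
  expect_equal(fit2$observed_stat, fit$observed_stat, tolerance = 1e-12)
  expect_error(rda_permutation_test(Y, X, n_perm = 50), "99")
})

test_that("tidy and glance expose axes and the test summary", {
  set.seed(67)
  X <- matrix(rnorm(60), 30, 2)
  Y <- X %*% matrix(rnorm(6), 2, 3) + matrix(rnorm(90, sd = 0.3), 30, 3)
  fit <- rda_permutation_test(Y, X, n_perm = 99, seed = 3)
  td <- tidy(fit)
  expect_equal(names(td),
               c("axis", "eigenvalue", "proportion_pct", "cumulative_pct"))
  expect_true(all(diff(td$eigenvalue) <= 1e-12))
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_true(gl$p_value > 0 && gl$p_value <= 1)
})
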