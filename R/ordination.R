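#' Redundancy analysis of a response matrix on environmental predictors
#'
#' Constrained ordination: both matrices are centred (and by default the
#' responses standardised to unit variance, since forest descriptors mix
#' counts, m2/ha, percentages and an index), the responses are regressed
#' on the predictors, and the fitted values `Yhat = X (X'X)^-1 X' Y` are
#' eigen-decomposed. Each constrained axis explains
#' `eigenvalue / total variance of Y` of the total variation. Site scores
#' are returned both as linear combinations of the predictors (`lc`) and
#' as weighted averages of the responses (`wa`); biplot scores are the
#' correlations of the predictor columns with the `lc` site scores.
#'
#' @param Y Numeric matrix or data frame of responses (n x q), e.g. forest
#'   structure/composition descriptors per plot.
#' @param X Numeric matrix or data frame of predictors (n x p),
#'   environmental and anthropogenic variables.
#' @param standardise_y,standardise_x Scale columns to unit variance
#'   (defaults `TRUE` for both).
#' @param tol Relative tolerance used to flag collinear predictors.
#' @return An object of class `rch_rda` with eigenvalues, per-axis
#'   proportions of total variance, site scores (`lc`, `wa`), response
#'   scores, biplot scores and the total variance.
#' @export
#'
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' Y <- X %*% matrix(c(1, 0.5, -0.3, 0.8, 0, 1), 2, 3) + rnorm(60, sd = 0.1)
#' fit <- rda_fit(Y, X)
#' tidy(fit)
rda_fit <- function(Y, X, standardise_y = TRUE, standardise_x = TRUE,
                    tol = 1e-10) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (!is.numeric(Y) || !is.numeric(X)) stop("Y and X must be numeric", call. = FALSE)
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X must have the same number of rows", call. = FALSE)
  if (anyNA(Y) || anyNA(X)) stop("missing values are not allowed", call. = FALSE)
  if (n <= ncol(X) + 1) {
    stop("need more rows than predictors plus one", call. = FALSE)
  }
  Yc <- scale(Y, center = TRUE, scale = standardise_y)
  Xc <- scale(X, center = TRUE, scale = standardise_x)
  if (any(attr(Yc, "scaled:scale") == 0) || any(attr(Xc, "scaled:scale") == 0)) {
    stop("zero-variance column in Y or X", call. = FALSE)
  }
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qrX$pivot[(qrX$rank + 1):ncol(Xc)]] %||%
      qrX$pivot[(qrX$rank + 1):ncol(Xc)]
    stop("collinear predictor columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  Yhat <- qr.fitted(qrX, Yc)
  dec <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  r <- min(qrX$rank, ncol(Yc))
  lambda <- pmax(dec$values[seq_len(r)], 0)
  V <- dec$vectors[, seq_len(r), drop = FALSE]
  rownames(V) <- colnames(Yc) %||% paste0("Y", seq_len(ncol(Yc)))
  colnames(V) <- paste0("RDA", seq_len(r))
  total_var <- sum(apply(Yc, 2, var))
  site_lc <- Yhat %*% V
  site_wa <- Yc %*% V
  biplot <- suppressWarnings(cor(Xc, site_lc))
  biplot[!is.finite(biplot)] <- 0
  rownames(biplot) <- colnames(Xc) %||% paste0("X", seq_len(ncol(Xc)))
  structure(
    list(
      eigenvalues = lambda,
      proportion_pct = 100 * lambda / total_var,
      total_variance = total_var,
      constrained_variance = sum(lambda),
      site_scores_lc = site_lc,
      site_scores_wa = site_wa,
      response_scores = V,
      biplot_scores = biplot,
      n = n, p = ncol(Xc), q = ncol(Yc),
      standardise_y = standardise_y, standardise_x = standardise_x
    ),
    class = "rch_rda"
  )
}

#' @export
print.rch_rda <- function(x, ...) {
  cat(sprintf("<rch_rda> %d sites, %d responses, %d predictors\n",
              x$n, x$q, x$p))
  k <- min(4, length(x$eigenvalues))
  cat("  axis proportion of total variance (%):",
      paste(sprintf("%.1f", x$proportion_pct[seq_len(k)]), collapse = ", "),
      "\n")
  cat(sprintf("  constrained / total variance: %.1f%%\n",
              100 * x$constrained_variance / x$total_variance))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p-value: %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Per-axis eigenvalues and variance proportions
#' @param x An `rch_rda` fit.
#' @param ... Unused.
#' @return Tibble with `axis`, `eigenvalue`, `proportion_pct`,
#'   `cumulative_pct`.
#' @method tidy rch_rda
#' @export
tidy.rch_rda <- function(x, ...) {
  tibble::tibble(
    axis = paste0("RDA", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    proportion_pct = x$proportion_pct,
    cumulative_pct = cumsum(x$proportion_pct)
  )
}

#' One-row summary of an RDA fit
#' @param x An `rch_rda` fit.
#' @param ... Unused.
#' @return Tibble with dimensions, constrained share of variance and (when
#'   [rda_permutation_test()] has been attached) the permutation p-value.
#' @method glance rch_rda
#' @export
glance.rch_rda <- function(x, ...) {
  tibble::tibble(
    n = x$n, q = x$q, p = x$p,
    constrained_pct = 100 * x$constrained_variance / x$total_variance,
    axis1_pct = x$proportion_pct[1],
    axis2_pct = if (length(x$proportion_pct) > 1) x$proportion_pct[2] else NA_real_,
    p_value = x$p_value %||% NA_real_,
    n_permutations = x$n_permutations %||% NA_integer_
  )
}

#' Triplot of an RDA fit
#'
#' Sites as points, response variables as black arrows and predictor
#' biplot scores as coloured arrows on the first two constrained axes.
#'
#' @param object An `rch_rda` fit.
#' @param site_alpha Point transparency.
#' @param arrow_scale Multiplier applied to arrow coordinates.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rch_rda
#' @export
autoplot.rch_rda <- function(object, site_alpha = 0.4, arrow_scale = NULL, ...) {
  sites <- tibble::as_tibble(object$site_scores_wa[, 1:2, drop = FALSE],
                             .name_repair = ~ c("RDA1", "RDA2"))
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(as.matrix(sites)))
  }
  arr <- function(m, kind) {
    tibble::tibble(
      name = rownames(m),
      RDA1 = m[, 1] * arrow_scale, RDA2 = m[, 2] * arrow_scale,
      kind = kind
    )
  }
  arrows_df <- dplyr::bind_rows(
    arr(object$response_scores, "response"),
    arr(object$biplot_scores, "predictor")
  )
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$RDA1, y = .data$RDA2)) +
    ggplot2::geom_point(alpha = site_alpha, colour = "grey40") +
    ggplot2::geom_segment(
      data = arrows_df,
      ggplot2::aes(x = 0, y = 0, xend = .data$RDA1, yend = .data$RDA2,
                   colour = .data$kind),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = arrows_df,
      ggplot2::aes(label = .data$name, colour = .data$kind),
      size = 3, vjust = -0.4, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(response = "black",
                                            predictor = "steelblue")) +
    ggplot2::labs(
      x = sprintf("RDA1 (%.1f%%)", object$proportion_pct[1]),
      y = sprintf("RDA2 (%.1f%%)",
                  if (length(object$proportion_pct) > 1)
                    object$proportion_pct[2] else 0),
      colour = NULL
    )
}

#' Monte Carlo permutation test of the constrained variance
#'
#' The test statistic is the sum of the constrained eigenvalues. Rows of
#' the response matrix are permuted (raw-row permutation), the statistic
#' recomputed, and `p = (1 + #\{perm >= observed\}) / (1 + n_perm)` — the
#' add-one form never reports exactly zero.
#'
#' @inheritParams rda_fit
#' @param n_perm Number of permutations (at least 99; 10000 for a
#'   publication-grade test).
#' @param seed Integer RNG seed.
#' @return The `rch_rda` fit with `p_value`, `n_permutations` and the
#'   permutation statistics attached.
#' @export
rda_permutation_test <- function(Y, X, n_perm = 10000, seed = 1,
                                 standardise_y = TRUE, standardise_x = TRUE) {
  if (n_perm < 99) stop("use at least 99 permutations", call. = FALSE)
  fit <- rda_fit(Y, X, standardise_y, standardise_x)
  Yc <- scale(as.matrix(Y), center = TRUE, scale = standardise_y)
  Xc <- scale(as.matrix(X), center = TRUE, scale = standardise_x)
  qrX <- qr(Xc)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  stat_of <- function(M) sum(crossprod(Q, M)^2) / (nrow(M) - 1)
  observed <- stat_of(Yc)
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    stat_of(Yc[sample(nrow(Yc)), , drop = FALSE])
  }, numeric(1))
  fit$p_value <- (1 + sum(perm_stats >= observed)) / (1 + n_perm)
  fit$n_permutations <- as.integer(n_perm)
  fit$observed_stat <- observed
  fit$perm_stats <- perm_stats
  fit
}
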