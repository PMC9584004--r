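#' Accuracy metrics from a confusion matrix
#'
#' Remote-sensing convention: rows are the reference labels, columns the
#' predictions. User's accuracy of a class is its precision
#' (`diag / column sum`), producer's accuracy its recall
#' (`diag / row sum`); overall accuracy is `trace / N` and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with `p_e = sum(row_i * col_i) / N^2`.
#' Classes with a zero marginal report `NA` for that accuracy.
#'
#' @param confusion Square numeric matrix of counts, reference x predicted.
#' @return A list with `overall`, named vectors `users` and `producers`,
#'   `kappa`, and the matrix itself.
#' @export
#'
#' @examples
#' accuracy_metrics(matrix(c(45, 10, 5, 40), 2))  # overall 0.85, kappa 0.70
accuracy_metrics <- function(confusion) {
  confusion <- matrix(as.numeric(confusion), nrow(confusion), ncol(confusion),
                      dimnames = dimnames(confusion))
  if (nrow(confusion) != ncol(confusion)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  n <- sum(confusion)
  if (n <= 0) stop("confusion matrix total must be positive", call. = FALSE)
  if (any(confusion < 0)) stop("confusion entries must be non-negative", call. = FALSE)
  d <- diag(confusion)
  rs <- rowSums(confusion)
  cs <- colSums(confusion)
  users <- ifelse(cs > 0, d / cs, NA_real_)
  producers <- ifelse(rs > 0, d / rs, NA_real_)
  p_o <- sum(d) / n
  p_e <- sum(rs * cs) / n^2
  kappa <- if (p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  cls <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  list(
    overall = p_o,
    users = setNames(users, cls),
    producers = setNames(producers, cls),
    kappa = kappa,
    confusion = confusion
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

impute_median <- function(df, medians = NULL) {
  if (is.null(medians)) {
    medians <- vapply(df, function(x) stats::median(x[is.finite(x)]), numeric(1))
  }
  for (nm in names(df)) {
    bad <- !is.finite(df[[nm]])
    if (any(bad)) df[[nm]][bad] <- medians[[nm]]
  }
  list(df = df, medians = medians)
}

#' Train a random-forest object classifier
#'
#' Bootstrap-aggregated decision trees via \pkg{ranger} with
#' `floor(sqrt(p))` candidate features per split, probability output, and
#' deterministic behaviour under a fixed seed. Missing or non-finite
#' feature values are imputed with the training medians (stored in the
#' model for reuse at prediction).
#'
#' @param features Data frame / tibble of numeric object features.
#' @param labels Factor (or coercible) with one label per row; at least two
#'   classes with two examples each.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer RNG seed.
#' @param probability Grow a probability forest (default). With `FALSE` a
#'   response forest is grown and the out-of-bag `prediction.error` is the
#'   misclassification rate rather than the Brier score.
#' @return An object of class `rch_classifier`.
#' @export
train_classifier <- function(features, labels, n_trees = 500, seed = 1,
                             probability = TRUE) {
  features <- tibble::as_tibble(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("labels must contain at least two classes", call. = FALSE)
  if (any(table(labels) < 2)) stop("each class needs at least two examples", call. = FALSE)
  imp <- impute_median(features)
  dat <- dplyr::bind_cols(imp$df, .class = labels)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = as.data.frame(dat),
    num.trees = n_trees, mtry = max(1, floor(sqrt(ncol(features)))),
    probability = probability, seed = seed, num.threads = 1,
    respect.unordered.factors = TRUE
  )
  structure(
    list(fit = fit, medians = imp$medians, levels = levels(labels),
         n_trees = n_trees, seed = seed, probability = probability),
    class = "rch_classifier"
  )
}

#' @export
print.rch_classifier <- function(x, ...) {
  cat(sprintf("<rch_classifier> random forest, %d trees, classes: %s\n",
              x$n_trees, paste(x$levels, collapse = ", ")))
  cat(sprintf("  OOB prediction error: %.4f\n", x$fit$prediction.error))
  invisible(x)
}

#' Predict class labels and probabilities
#'
#' @param object An `rch_classifier`.
#' @param newdata Feature data frame.
#' @param ... Unused.
#' @return Tibble with `.pred_class` and one probability column per class.
#' @export
predict.rch_classifier <- function(object, newdata, ...) {
  imp <- impute_median(tibble::as_tibble(newdata), object$medians)
  pr <- stats::predict(object$fit, data = as.data.frame(imp$df),
                       num.threads = 1)$predictions
  if (!isTRUE(object$probability)) {
    return(tibble::tibble(.pred_class = factor(pr, object$levels)))
  }
  cls <- object$levels[max.col(pr, ties.method = "first")]
  out <- tibble::as_tibble(as.data.frame(pr))
  names(out) <- paste0(".prob_", colnames(pr))
  dplyr::bind_cols(tibble::tibble(.pred_class = factor(cls, object$levels)), out)
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the object classifier
#'
#' Folds are stratified by class; user's, producer's and overall accuracy
#' and Cohen's kappa are computed on each held-out fold and averaged, and
#' the pooled confusion matrix over all folds is reported alongside.
#'
#' @inheritParams train_classifier
#' @param k Number of folds (default 5).
#' @return An object of class `rch_cv_report`: per-fold metrics tibble,
#'   their means, and the pooled confusion matrix with its metrics.
#' @export
cross_validate <- function(features, labels, k = 5, n_trees = 500, seed = 1) {
  features <- tibble::as_tibble(features)
  labels <- factor(labels)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (any(table(labels) < k)) {
    stop("each class needs at least k examples for stratified folds", call. = FALSE)
  }
  fold <- stratified_folds(labels, k, seed)
  lev <- levels(labels)
  pooled <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_classifier(features[tr, , drop = FALSE], labels[tr],
                              n_trees = n_trees, seed = seed + f)
    pred <- predict(model, features[!tr, , drop = FALSE])$.pred_class
    cm <- table(factor(labels[!tr], lev), factor(pred, lev))
    pooled <- pooled + cm
    m <- accuracy_metrics(cm)
    per_fold[[f]] <- tibble::tibble(
      fold = f, overall = m$overall, kappa = m$kappa,
      class = lev, users = m$users, producers = m$producers
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  fold_level <- dplyr::distinct(per_fold, .data$fold, .data$overall, .data$kappa)
  means <- list(
    overall = mean(fold_level$overall),
    kappa = mean(fold_level$kappa),
    users = tapply(per_fold$users, per_fold$class, mean)[lev],
    producers = tapply(per_fold$producers, per_fold$class, mean)[lev]
  )
  structure(
    list(per_fold = per_fold, means = means,
         pooled = accuracy_metrics(pooled), k = k, seed = seed),
    class = "rch_cv_report"
  )
}

#' @export
print.rch_cv_report <- function(x, ...) {
  cat(sprintf("<rch_cv_report> %d-fold stratified cross-validation\n", x$k))
  cat(sprintf("  mean overall accuracy: %.3f   mean kappa: %.3f\n",
              x$means$overall, x$means$kappa))
  cat("  pooled confusion (reference rows x predicted columns):\n")
  print(x$pooled$confusion)
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-class fold-averaged accuracies of a cross-validation report
#' @param x An `rch_cv_report`.
#' @param ... Unused.
#' @return Tibble with one row per class: mean user's and producer's
#'   accuracy across folds.
#' @method tidy rch_cv_report
#' @export
tidy.rch_cv_report <- function(x, ...) {
  tibble::tibble(
    class = names(x$means$users),
    users_accuracy = as.numeric(x$means$users),
    producers_accuracy = as.numeric(x$means$producers)
  )
}

#' One-row summary of a cross-validation report
#' @param x An `rch_cv_report`.
#' @param ... Unused.
#' @return Tibble with mean overall accuracy, mean kappa, pooled overall
#'   accuracy and pooled kappa.
#' @method glance rch_cv_report
#' @export
glance.rch_cv_report <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    overall_accuracy = x$means$overall,
    kappa = x$means$kappa,
    pooled_overall = x$pooled$overall,
    pooled_kappa = x$pooled$kappa
  )
}
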