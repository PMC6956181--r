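#' Stratified fold assignment
#'
#' Shuffles instances within each class (seeded) and deals them round-robin
#' into `k` folds, so per-fold class proportions stay within one instance of
#' the global proportions and folds form a disjoint cover.
#'
#' @param class factor of instance classes.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k), one per instance.
#' @export
stratified_folds <- function(class, k = 10, seed = 1L) {
  stopifnot(length(class) >= k)
  fold <- integer(length(class))
  with_seed(seed, {
    for (lv in levels(factor(class))) {
      idx <- sample(which(class == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# quality indicators from pooled class-probability predictions:
# P = predicted probability matrix, truth = factor, B = baseline (prior)
# probability matrix of the same shape
quality_indicators <- function(P, truth, B, levels) {
  Y <- onehot(truth, levels)
  pred <- factor(levels[max.col(P, ties.method = "first")], levels = levels)
  mae <- mean(abs(P - Y))
  rmse <- sqrt(mean((P - Y)^2))
  mae_base <- mean(abs(B - Y))
  rmse_base <- sqrt(mean((B - Y)^2))
  cm <- table(truth = truth, predicted = pred)
  list(correctly_classified_pct = 100 * mean(pred == truth),
       incorrectly_classified_pct = 100 * mean(pred != truth),
       mean_absolute_error = mae,
       root_mean_squared_error = rmse,
       relative_absolute_error_pct = 100 * mae / mae_base,
       root_relative_squared_error_pct = 100 * rmse / rmse_base,
       confusion_matrix = cm,
       n_evaluated = length(truth))
}

prior_matrix <- function(train_class, n, levels) {
  pr <- as.numeric(table(factor(train_class, levels = levels))) /
    length(train_class)
  matrix(pr, nrow = n, ncol = length(levels), byrow = TRUE)
}

#' Evaluate a classifier under a study protocol
#'
#' Three protocols:
#' * `training` — fit on the full dataset and test on it.
#' * `cv10` — stratified 10-fold cross-validation with seeded shuffling;
#'   per-instance predictions are pooled over folds before computing the
#'   indicators.
#' * `split75` — seeded stratified 75/25 split; fit on 75%, test on 25%.
#'
#' Six quality indicators are reported: correctly / incorrectly classified
#' instance percentages, mean absolute error and root mean squared error of
#' the class-probability vectors against one-hot truth, and their relative
#' versions (RAE, RRSE) normalized by a prior-probability baseline classifier
#' fitted on the corresponding training data. The 2x2 confusion matrix is
#' attached.
#'
#' @param kind classifier kind, see [train_classifier()].
#' @param d a `feature_dataset`.
#' @param protocol `"training"`, `"cv10"` or `"split75"`.
#' @param seed integer seed driving fold/split shuffling and the classifier.
#' @param ... passed to [train_classifier()].
#' @return An `eval_report`: list with `protocol`, `kind`, `meter`, the six
#'   indicators, `confusion_matrix`, `n_evaluated`, `seed`.
#' @export
evaluate_classifier <- function(kind, d,
                                protocol = c("training", "cv10", "split75"),
                                seed = 1L, ...) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(d, "feature_dataset"))
  n <- nrow(d$x)
  levels <- levels(d$class)

  if (protocol == "training") {
    model <- train_classifier(kind, d, seed = seed, ...)
    pr <- predict_cry(model, d$x)
    q <- quality_indicators(pr$prob, d$class,
                            prior_matrix(d$class, n, levels), levels)
  } else if (protocol == "cv10") {
    if (n < 10) stop("cv10 needs >= 10 instances", call. = FALSE)
    fold <- stratified_folds(d$class, 10, seed)
    P <- matrix(NA_real_, n, length(levels))
    B <- matrix(NA_real_, n, length(levels))
    for (f in seq_len(10)) {
      test <- fold == f
      if (!any(test)) next   # small datasets can leave late folds empty
      dt <- feature_dataset(d$x[!test, , drop = FALSE], d$class[!test],
                            d$meter, d$attribute_names)
      model <- train_classifier(kind, dt, seed = derive_seed(seed, f), ...)
      P[test, ] <- predict_cry(model, d$x[test, , drop = FALSE])$prob
      B[test, ] <- prior_matrix(dt$class, sum(test), levels)
    }
    q <- quality_indicators(P, d$class, B, levels)
  } else {
    test <- rep(TRUE, n)
    with_seed(seed, {
      for (lv in levels) {
        idx <- sample(which(d$class == lv))
        n_train <- max(1, floor(0.75 * length(idx)))
        test[idx[seq_len(n_train)]] <- FALSE
      }
    })
    if (!any(test) || all(test))
      stop("split75 needs a non-empty train and test part", call. = FALSE)
    dt <- feature_dataset(d$x[!test, , drop = FALSE], d$class[!test],
                          d$meter, d$attribute_names)
    model <- train_classifier(kind, dt, seed = seed, ...)
    pr <- predict_cry(model, d$x[test, , drop = FALSE])
    q <- quality_indicators(pr$prob, d$class[test],
                            prior_matrix(dt$class, sum(test), levels), levels)
  }

  structure(c(list(protocol = protocol, kind = kind, meter = d$meter),
              q, list(seed = seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Classifier: %s  (%s, protocol %s, seed %d)\n",
              x$kind, x$meter, x$protocol, x$seed))
  cat(sprintf("  Correctly classified instances    %.2f%%\n",
              x$correctly_classified_pct))
  cat(sprintf("  Incorrectly classified instances  %.2f%%\n",
              x$incorrectly_classified_pct))
  cat(sprintf("  Mean absolute error               %.4f\n",
              x$mean_absolute_error))
  cat(sprintf("  Root mean squared error           %.4f\n",
              x$root_mean_squared_error))
  cat(sprintf("  Relative absolute error           %.2f%%\n",
              x$relative_absolute_error_pct))
  cat(sprintf("  Root relative squared error       %.2f%%\n",
              x$root_relative_squared_error_pct))
  cat("  Confusion matrix (rows = truth):\n")
  print(x$confusion_matrix)
  invisible(x)
}
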