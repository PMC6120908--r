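# Precision-recall evaluation. Average precision is the step-wise sum
# AP = sum_i (recall_i - recall_{i-1}) * precision_i with recall_0 = 0,
# thresholds enumerated at every distinct score (descending); tied scores
# enter at a single threshold.

#' Precision-recall curve
#'
#' Enumerates one threshold per distinct score, descending. At each
#' threshold t, samples with score >= t are predicted positive and
#' precision = TP / (TP + FP), recall = TP / (TP + FN).
#'
#' @param scores Numeric ranking statistic (higher = more case-like).
#' @param labels Binary labels (1 = case / positive).
#' @return A `pr_curve` tibble with columns threshold, precision, recall;
#'   recall is non-decreasing down the rows.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  if (!all(is.finite(scores))) abort("Scores must be finite.")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0) abort("At least one positive label is required.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  last_of_tie <- c(diff(s) != 0, TRUE)
  out <- tibble::tibble(
    threshold = s[last_of_tie],
    precision = tp[last_of_tie] / (tp[last_of_tie] + fp[last_of_tie]),
    recall = tp[last_of_tie] / n_pos
  )
  class(out) <- c("pr_curve", class(out))
  out
}

#' Average precision
#'
#' Summary of a precision-recall curve: the precision at each threshold
#' weighted by the increase in recall from the previous threshold.
#'
#' @param x Either a `pr_curve` (from [pr_curve()]) or a numeric score
#'   vector (then `labels` is required).
#' @param labels Binary labels, when `x` is a score vector.
#' @return A single number in \[0, 1\].
#' @export
average_precision <- function(x, labels = NULL) {
  curve <- if (inherits(x, "pr_curve")) x else pr_curve(x, labels)
  sum(diff(c(0, curve$recall)) * curve$precision)
}

#' Mean average precision across CV splits
#'
#' Arithmetic mean and sample standard deviation of per-split AP, reported
#' on the 0-100 scale.
#'
#' @param ap Numeric vector of per-split AP values on \[0, 1\], or a data
#'   frame with an `ap` column (e.g. the output of [repeated_nested_cv()]).
#' @return Tibble with columns map, sd, n_splits (map and sd on 0-100).
#' @export
mean_average_precision <- function(ap) {
  if (is.data.frame(ap)) ap <- ap$ap
  if (length(ap) == 0) abort("At least one split is required.")
  tibble::tibble(
    map = 100 * mean(ap),
    sd = if (length(ap) > 1) 100 * sd(ap) else 0,
    n_splits = length(ap)
  )
}

#' Overall accuracy
#'
#' Percentage of correctly classified instances.
#'
#' @param predicted,labels Equal-length binary vectors.
#' @return Accuracy in percent (0-100).
#' @export
overall_accuracy <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  if (length(labels) == 0) abort("Empty input.")
  100 * mean(as.integer(predicted) == as.integer(labels))
}

#' Linear-SVM back-end: train and score
#'
#' Fits a maximum-margin classifier with the linear kernel
#' `k(x_i, x_j) = x_i' x_j` on dosage features (no rescaling: dosages share
#' a scale) and returns continuous decision values for the test samples,
#' oriented so larger = more case-like. AP needs a ranking, not hard labels;
#' use [svm_train_classify()] when class predictions are wanted.
#'
#' @param train_x,test_x Numeric matrices (samples x SNPs) or genotype
#'   tibbles restricted to the same SNPs.
#' @param train_y Binary training labels (both classes required).
#' @param cost Soft-margin cost parameter C.
#' @return Numeric decision scores for the rows of `test_x`.
#' @export
svm_train_predict <- function(train_x, train_y, test_x, cost = 1) {
  train_x <- as_feature_matrix(train_x)
  test_x <- as_feature_matrix(test_x)
  train_y <- as.integer(train_y)
  if (length(unique(train_y)) < 2) {
    abort("SVM training requires both classes.")
  }
  fit <- e1071::svm(train_x, factor(train_y, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  pred <- predict(fit, test_x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  d <- dv[, 1]
  # libsvm reports the decision value for the "<first>/<second>" class pair;
  # orient so positive values favour class 1.
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first != "1") d <- -d
  unname(d)
}

#' @rdname svm_train_predict
#' @return For [svm_train_classify()], predicted 0/1 labels.
#' @export
svm_train_classify <- function(train_x, train_y, test_x, cost = 1) {
  as.integer(svm_train_predict(train_x, train_y, test_x, cost = cost) > 0)
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    if (all(geno_meta_cols %in% names(x))) return(dosage_matrix(x))
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    return(m)
  }
  abort("Expected a matrix, data frame or genotype tibble.")
}
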