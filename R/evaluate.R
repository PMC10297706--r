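#' Confusion-matrix metrics for binary predictions
#'
#' Positive class is the disease label 1. Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n. If a class is absent from
#' `labels`, the corresponding rate is undefined and returned as `NA` with a
#' warning.
#'
#' @param labels binary 0/1 vector of true outcomes.
#' @param predictions binary 0/1 vector of hard predictions.
#' @return list with `sensitivity`, `specificity`, `accuracy`, and `counts`
#'   (named vector tp, fp, tn, fn).
#' @export
confusion_metrics <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions),
            all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fn <- sum(labels == 1 & predictions == 0)
  sens <- if (tp + fn == 0) {
    warning("no positive labels; sensitivity undefined"); NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative labels; specificity undefined"); NA_real_
  } else tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(labels),
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps all score thresholds from high to low, grouping tied scores, and
#' returns the ROC points and the trapezoidal area. The area is cross-checked
#' internally against the tie-corrected Mann-Whitney rank form
#' U / (n1 * n0); a disagreement beyond 1e-10 is an internal error.
#'
#' @param labels binary 0/1 vector; both classes must be present.
#' @param scores finite numeric scores (higher = more likely positive).
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`, starting
#'   at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(is.finite(scores)),
            all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("ROC requires both classes in labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  pts <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
                    threshold = c(Inf, s[last_of_group]))
  auc_trap <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  # Mann-Whitney with midranks (ties count 1/2)
  r <- rank(scores)
  auc_u <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (abs(auc_trap - auc_u) > 1e-10) {
    stop("internal error: trapezoidal and rank-statistic AUC disagree")
  }
  list(points = pts, auc = auc_trap)
}

#' Train on the selected factor subset and evaluate on the held-out test set
#'
#' The model family is fitted on the (SMOTE-balanced) training matrix
#' restricted to `subset`; hard predictions on the untouched test partition
#' use a 0.5 probability threshold. SMOTE never touches the test rows, so all
#' metrics reflect the original class imbalance.
#'
#' @param family a [model_family()].
#' @param subset character vector of factor names to use (non-empty).
#' @param train_x,train_y training features (matrix/data.frame with named
#'   columns) and 0/1 labels, typically post-SMOTE.
#' @param test_x,test_y held-out features and labels.
#' @param method label recorded in the report (e.g. `"ttest"` or `"shap"`).
#' @param seed integer seed (some families consume randomness when fitting).
#' @return an `evaluation_report`: list with `model`, `method`, `subset`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc`, `roc` (points
#'   data.frame), and `counts`.
#' @export
evaluate_final <- function(family, subset, train_x, train_y, test_x, test_y,
                           method = NA_character_, seed = 1L) {
  stopifnot(length(subset) >= 1)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  stopifnot(all(subset %in% colnames(train_x)),
            all(subset %in% colnames(test_x)))
  local_seed(seed, {
    fit <- family$fit(train_x[, subset, drop = FALSE], train_y)
    prob <- family$predict_prob(fit, test_x[, subset, drop = FALSE])
  })
  pred <- as.integer(prob >= 0.5)
  cm <- confusion_metrics(test_y, pred)
  roc <- roc_auc(test_y, prob)
  structure(list(model = family$id, method = method, subset = subset,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 accuracy = cm$accuracy, auc = roc$auc, roc = roc$points,
                 counts = cm$counts),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (%s): sens %.3f spec %.3f AUC %.3f acc %.3f | factors: %s\n",
              x$model, x$method, x$sensitivity, x$specificity, x$auc,
              x$accuracy, paste(x$subset, collapse = ", ")))
  invisible(x)
}
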