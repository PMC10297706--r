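#' Convert a ranking to integer weights
#'
#' The factor at 1-based rank r receives weight d - r: the top factor gets
#' d - 1 and the bottom factor 0, so later zeroing a removed factor's weight
#' is consistent with the bottom of the ranking.
#'
#' @param ranking a `ranking` data.frame (from [rank_by_ttest()] or
#'   [rank_by_shapley()]).
#' @param d number of risk factors; must equal `nrow(ranking)`.
#' @return named numeric vector of weights, in ranking order.
#' @export
assign_weights <- function(ranking, d = nrow(ranking)) {
  stopifnot(nrow(ranking) == d)
  if (anyDuplicated(ranking$factor)) stop("duplicate factors in ranking")
  stats::setNames(d - seq_len(d), ranking$factor)
}

#' Cross-validated AUC of one model family on a factor subset
#'
#' Mean ROC-AUC over stratified folds. Fold assignment is per class, so every
#' fold contains both classes; the model is refit on each training fold and
#' scored on the held-out fold.
#'
#' @param family a [model_family()].
#' @param features numeric matrix restricted to the candidate factor subset.
#' @param labels 0/1 vector.
#' @param folds number of folds (>= 2; default 5).
#' @param seed integer seed (fold assignment and model randomness).
#' @return mean AUC in [0,1].
#' @export
cv_auc <- function(family, features, labels, folds = 5L, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(ncol(features) >= 1, folds >= 2, all(labels %in% c(0, 1)))
  fold_id <- integer(length(labels))
  local_seed(seed, {
    for (cl in c(0, 1)) {
      ix <- which(labels == cl)
      fold_id[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- family$fit(features[tr, , drop = FALSE], labels[tr])
      prob <- family$predict_prob(fit, features[!tr, , drop = FALSE])
      roc_auc(labels[!tr], prob)$auc
    }, 0)
  })
  mean(aucs)
}

#' Greedy cross-validated-AUC elimination over a ranked factor list
#'
#' Scans the factors in rank order, maintaining a cumulative kept set
#' (initially empty) and `prev_AUC = 0`. For each factor, `curr_AUC` is the
#' cross-validated AUC of the kept set plus that factor; if
#' `prev_AUC >= curr_AUC` the factor is removed and its weight set to zero,
#' otherwise it joins the kept set and `prev_AUC` is updated. The first
#' ranked factor is therefore always kept whenever its AUC is positive.
#'
#' @param family a [model_family()].
#' @param ranking a `ranking` ordered by the family's ranking method.
#' @param weights named weight vector from [assign_weights()].
#' @param features full training feature matrix (named columns).
#' @param labels 0/1 training labels.
#' @param folds,seed passed to [cv_auc()]; the whole scan shares one fold
#'   assignment so successive AUCs are compared on identical folds.
#' @return list with `weights` (updated: original value or 0) and `trace`
#'   (data.frame `step`, `factor`, `prev_auc`, `curr_auc`, `decision`).
#' @export
greedy_select <- function(family, ranking, weights, features, labels,
                          folds = 5L, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(all(ranking$factor %in% colnames(features)),
            setequal(names(weights), ranking$factor))
  kept <- character(0)
  prev_auc <- 0
  trace <- vector("list", nrow(ranking))
  # one fold assignment for the whole scan: candidate AUCs are paired
  # comparisons on identical folds, not resampled per step
  cv_seed <- derive_seed(seed, "cv")
  for (step in seq_len(nrow(ranking))) {
    fac <- ranking$factor[step]
    prev_before <- prev_auc
    curr_auc <- cv_auc(family, features[, c(kept, fac), drop = FALSE], labels,
                       folds = folds, seed = cv_seed)
    if (prev_auc >= curr_auc) {
      weights[fac] <- 0
      decision <- "removed"
    } else {
      kept <- c(kept, fac)
      prev_auc <- curr_auc
      decision <- "kept"
    }
    trace[[step]] <- data.frame(step = step, factor = fac,
                                prev_auc = prev_before,
                                curr_auc = curr_auc, decision = decision)
  }
  list(weights = weights, trace = do.call(rbind, trace), kept = kept)
}

#' Average per-model, per-repeat weights into the ensemble weight vector
#'
#' The final per-factor weight is the plain mean of the post-greedy weights
#' over all classifier families and repeats (equal model weights); the
#' ensemble ranking orders factors by descending final weight, ties broken by
#' ascending factor name.
#'
#' @param weight_list list of named weight vectors (one per family x repeat),
#'   all covering the same factors.
#' @return list with `weights` (named mean vector) and `ranking` (a `ranking`
#'   data.frame with `score` = ensemble weight).
#' @export
ensemble_weights <- function(weight_list) {
  stopifnot(length(weight_list) >= 1)
  facs <- sort(names(weight_list[[1]]))
  for (w in weight_list) {
    if (!setequal(names(w), facs)) stop("mismatched factor sets in weight vectors")
  }
  m <- vapply(weight_list, function(w) w[facs], numeric(length(facs)))
  avg <- rowMeans(as.matrix(m))
  out <- data.frame(factor = facs, score = unname(avg))
  out <- out[order(-out$score, out$factor), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
  attr(out, "method") <- "ensemble"
  class(out) <- c("ranking", class(out))
  list(weights = stats::setNames(avg, facs), ranking = out)
}

#' Best ranking prefix by cross-validated AUC
#'
#' Evaluates the cross-validated AUC of each prefix of the ranking (top-1,
#' top-2, ..., all factors) and returns the prefix with the maximal AUC,
#' preferring the smallest prefix on ties.
#'
#' @param family a [model_family()].
#' @param ranking a `ranking` (typically the ensemble ranking).
#' @param features,labels training data.
#' @param folds,seed passed to [cv_auc()].
#' @return list with `subset` (factor names), `auc`, and `prefix_aucs`
#'   (data.frame `size`, `factor_added`, `auc`).
#' @export
best_prefix <- function(family, ranking, features, labels, folds = 5L, seed = 1L) {
  stopifnot(nrow(ranking) >= 1)
  features <- as.matrix(features)
  cv_seed <- derive_seed(seed, "prefix")  # identical folds across prefixes
  aucs <- vapply(seq_len(nrow(ranking)), function(m) {
    cv_auc(family, features[, ranking$factor[seq_len(m)], drop = FALSE],
           labels, folds = folds, seed = cv_seed)
  }, 0)
  best <- which.max(aucs)  # first maximum = smallest prefix on ties
  list(subset = ranking$factor[seq_len(best)], auc = aucs[best],
       prefix_aucs = data.frame(size = seq_along(aucs),
                                factor_added = ranking$factor, auc = aucs))
}
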