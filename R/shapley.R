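#' Retrain-based Shapley value function (subset-model table)
#'
#' The value function behind the Shapley attributions: for a feature subset
#' S, `f_S` is the model family refit on columns S only, evaluated as the
#' positive-class probability; `f_empty` is the constant training positive
#' rate. Models are trained lazily and cached, so the exact enumerator and
#' the Monte Carlo estimator share identical subset models. Each subset's
#' training consumes a seed derived from the table seed and the subset, so
#' the table contents do not depend on the order in which subsets are
#' requested.
#'
#' @param features numeric matrix (training rows, named columns; fully
#'   numeric and class-balanced, i.e. post-SMOTE).
#' @param labels 0/1 training labels.
#' @param family a [model_family()].
#' @param seed integer seed governing all subset-model training.
#' @return a `value_table` object.
#' @export
value_table <- function(features, labels, family, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(!is.null(colnames(features)), all(labels %in% c(0, 1)))
  vt <- new.env(parent = emptyenv())
  vt$d <- ncol(features)
  vt$col_names <- colnames(features)
  vt$seed <- as.integer(seed)
  vt$family_id <- family$id
  vt$cache <- new.env(parent = emptyenv())
  base_rate <- mean(labels)
  vt$predictor <- function(cols) {
    key <- paste0("S:", paste(sort(cols), collapse = ","))
    if (!is.null(vt$cache[[key]])) return(vt$cache[[key]])
    f <- if (length(cols) == 0) {
      function(x) rep(base_rate, nrow(x))
    } else {
      cols <- sort(cols)
      fit <- tryCatch(
        local_seed(derive_seed(seed, paste0("subset:", key)),
                   family$fit(features[, cols, drop = FALSE], labels)),
        error = function(e) {
          stop("training failed on subset {", key, "}: ", conditionMessage(e))
        })
      function(x) family$predict_prob(fit, x[, cols, drop = FALSE])
    }
    vt$cache[[key]] <- f
    f
  }
  class(vt) <- "value_table"
  vt
}

#' Construct a value table directly from a set function
#'
#' For testing and for analytic games: `f(cols, x)` must return one value per
#' row of `x` given the included column indices `cols` (possibly empty).
#'
#' @param d number of features.
#' @param f function(cols, x) -> numeric vector.
#' @param col_names optional feature names (default `f1..fd`).
#' @return a `value_table`.
#' @export
value_table_from_function <- function(d, f, col_names = paste0("f", seq_len(d))) {
  vt <- new.env(parent = emptyenv())
  vt$d <- d
  vt$col_names <- col_names
  vt$seed <- NA_integer_
  vt$family_id <- "function"
  vt$cache <- new.env(parent = emptyenv())
  vt$predictor <- function(cols) {
    cols <- sort(cols)
    function(x) f(cols, x)
  }
  class(vt) <- "value_table"
  vt
}

#' Eagerly train subset models
#'
#' Materializes the value function `f_S` for each requested subset (training
#' the family on those columns) and returns the backing [value_table()].
#' `f_empty` is the constant training positive-class rate.
#'
#' @inheritParams value_table
#' @param subsets list of integer column-index vectors (each a subset of
#'   `1:ncol(features)`; `integer(0)` is the empty set).
#' @return a `value_table` with the requested subsets cached.
#' @export
fit_subset_models <- function(family, features, labels, subsets, seed = 1L) {
  vt <- value_table(features, labels, family, seed = seed)
  for (s in subsets) {
    stopifnot(all(s %in% seq_len(vt$d)))
    vt$predictor(as.integer(s))
  }
  vt
}

# All-subset prediction matrix: rows = bitmask 0..2^d-1 (bit i-1 set <=>
# column i included), columns = evaluation instances.
subset_pred_matrix <- function(vt, x_eval) {
  d <- vt$d
  n_mask <- 2L^d
  p <- matrix(NA_real_, n_mask, nrow(x_eval))
  for (mask in 0:(n_mask - 1L)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) > 0L)
    p[mask + 1L, ] <- vt$predictor(cols)(x_eval)
  }
  p
}

#' Exact Shapley attributions by full subset enumeration
#'
#' Computes, for every evaluation instance x and feature i,
#' `phi_i(x) = sum over S not containing i of
#' |S|! (d-|S|-1)! / d! * (f_{S+i}(x) - f_S(x))`, requiring the model retrained
#' on every one of the 2^d feature subsets. The attribution target is the
#' positive-class probability. The efficiency axiom
#' `sum_i phi_i(x) = f_F(x) - f_empty` holds by construction up to float
#' round-off.
#'
#' @param vt a [value_table()] (all subsets will be trained/looked up).
#' @param x_eval numeric matrix of evaluation instances (named columns
#'   matching the table).
#' @return a `shapley_attribution`: list with `phi` (n_eval x d matrix),
#'   `global` (named mean |phi_i| per factor), `base` (f_empty per instance),
#'   `full` (f_F per instance), `mode = "exact"`.
#' @export
shapley_exact <- function(vt, x_eval) {
  x_eval <- as.matrix(x_eval)
  d <- vt$d
  stopifnot(d >= 1, ncol(x_eval) == d)
  p <- subset_pred_matrix(vt, x_eval)
  pop <- vapply(0:(2L^d - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) > 0L), 0L)
  w <- factorial(0:(d - 1L)) * factorial(d - 1L - (0:(d - 1L))) / factorial(d)
  phi <- matrix(0, nrow(x_eval), d)
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(2L^d - 1L), bit) == 0L)  # 1-based mask+1
    wt <- w[pop[without] + 1L]
    phi[, i] <- drop(crossprod(p[without + bit, , drop = FALSE] -
                                 p[without, , drop = FALSE], wt))
  }
  colnames(phi) <- vt$col_names
  structure(list(phi = phi, global = colMeans(abs(phi)),
                 base = p[1, ], full = p[2L^d, ],
                 mode = "exact", family = vt$family_id),
            class = "shapley_attribution")
}

#' Monte Carlo Shapley attributions by permutation sampling
#'
#' Estimates each `phi_i` as the average, over sampled feature orderings, of
#' feature i's marginal contribution `f_{prefix+i}(x) - f_prefix(x)`. Subset
#' models are trained lazily and cached, so repeated prefixes cost nothing.
#' The estimator is unbiased for the exact value, and the per-permutation sum
#' telescopes, so `sum_i phihat_i(x) = f_F(x) - f_empty(x)` exactly for any
#' number of permutations.
#'
#' @inheritParams shapley_exact
#' @param n_permutations number of sampled orderings (>= 1).
#' @param seed seed for the permutation draw.
#' @param permutations optional list of explicit orderings (overrides
#'   sampling; used to enumerate all d! orderings).
#' @return a `shapley_attribution` with `mode = "permutation"`, plus
#'   `n_permutations` and `se` (Monte Carlo standard error per factor of the
#'   global mean-|phi|-free raw estimate, averaged over instances).
#' @export
shapley_permutation <- function(vt, x_eval, n_permutations = 200L, seed = 1L,
                                permutations = NULL) {
  x_eval <- as.matrix(x_eval)
  d <- vt$d
  stopifnot(ncol(x_eval) == d)
  if (is.null(permutations)) {
    stopifnot(n_permutations >= 1)
    permutations <- local_seed(seed, {
      lapply(seq_len(n_permutations), function(i) sample.int(d))
    })
  }
  n_perm <- length(permutations)
  n_eval <- nrow(x_eval)
  phi <- matrix(0, n_eval, d)
  phi2 <- matrix(0, n_eval, d)
  for (perm in permutations) {
    prev <- vt$predictor(integer(0))(x_eval)
    cols <- integer(0)
    for (i in perm) {
      cols <- c(cols, i)
      cur <- vt$predictor(cols)(x_eval)
      phi[, i] <- phi[, i] + (cur - prev)
      phi2[, i] <- phi2[, i] + (cur - prev)^2
      prev <- cur
    }
  }
  phi_hat <- phi / n_perm
  mc_var <- pmax(phi2 / n_perm - phi_hat^2, 0) / max(n_perm - 1, 1)
  colnames(phi_hat) <- vt$col_names
  structure(list(phi = phi_hat, global = colMeans(abs(phi_hat)),
                 base = vt$predictor(integer(0))(x_eval),
                 full = vt$predictor(seq_len(d))(x_eval),
                 mode = "permutation", family = vt$family_id,
                 n_permutations = n_perm,
                 se = sqrt(colMeans(mc_var))),
            class = "shapley_attribution")
}

#' Shapley attributions for one model family
#'
#' Convenience wrapper: builds the retraining value table and dispatches to
#' exact enumeration (auto-selected for d <= 12) or Monte Carlo permutation
#' sampling.
#'
#' @inheritParams value_table
#' @param x_eval evaluation instances (e.g. held-out test rows).
#' @param mode `"auto"`, `"exact"`, or `"permutation"`.
#' @param n_permutations used in permutation mode.
#' @return a `shapley_attribution`.
#' @export
shapley_attribution <- function(features, labels, family, x_eval,
                                mode = c("auto", "exact", "permutation"),
                                n_permutations = 200L, seed = 1L) {
  mode <- match.arg(mode)
  vt <- value_table(features, labels, family, seed = seed)
  if (mode == "auto") mode <- if (vt$d <= 12) "exact" else "permutation"
  if (mode == "exact") {
    shapley_exact(vt, x_eval)
  } else {
    shapley_permutation(vt, x_eval, n_permutations = n_permutations,
                        seed = derive_seed(seed, "shap-perms"))
  }
}

#' Rank risk factors by global Shapley importance
#'
#' Global importance per factor is the mean absolute local value over the
#' evaluation instances; factors are ordered by descending importance (a
#' higher Shapley value denotes higher importance), ties broken by ascending
#' factor name.
#'
#' @param attribution a `shapley_attribution`.
#' @return a `ranking` data.frame (`rank`, `factor`, `score` = mean |phi|),
#'   attribute `method = "shap"`.
#' @export
rank_by_shapley <- function(attribution) {
  g <- attribution$global
  out <- data.frame(factor = names(g), score = unname(g))
  out <- out[order(-out$score, out$factor), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
  attr(out, "method") <- "shap"
  class(out) <- c("ranking", class(out))
  out
}
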