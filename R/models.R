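#' Classifier model families
#'
#' The five families used to validate and aggregate the risk-factor rankings:
#' k-nearest neighbours, decision tree, support vector machine (RBF kernel),
#' L2-free logistic regression, and Gaussian naive Bayes. Each family is a
#' uniform contract: `fit(x, y)` trains on a numeric matrix and 0/1 labels;
#' `predict_prob(fit, x)` returns the positive-class probability per row.
#' Families without native probabilities (the margin classifier) are
#' calibrated by a logistic link fitted on the training decision scores.
#'
#' Hyperparameters are baseline settings: k = 5 neighbours; an
#' impurity-grown tree with no complexity pruning; an RBF-kernel SVM with
#' default cost and gamma; unpenalized logistic regression; Gaussian naive
#' Bayes with variance smoothing.
#'
#' @param id one of `"knn"`, `"decision_tree"`, `"svm"`,
#'   `"logistic_regression"`, `"naive_bayes"`.
#' @return a `model_family` object: list with `id`, `fit`, `predict_prob`.
#' @export
model_family <- function(id = c("knn", "decision_tree", "svm",
                                "logistic_regression", "naive_bayes")) {
  id <- match.arg(id)
  fam <- switch(id,
    knn = list(
      fit = function(x, y) {
        list(x = as.matrix(x), y = as.integer(y), k = min(5L, nrow(x)))
      },
      # Vote share of the positive class among the k nearest training rows
      # (Euclidean). Distance ties are broken by training-row index, which
      # keeps predictions deterministic even on single binary columns where
      # almost all distances tie.
      predict_prob = function(fit, x) {
        x <- as.matrix(x)
        d2 <- outer(rowSums(x^2), rep(1, nrow(fit$x))) +
          outer(rep(1, nrow(x)), rowSums(fit$x^2)) -
          2 * tcrossprod(x, fit$x)
        idx <- apply(d2, 1, function(r) order(r)[seq_len(fit$k)])
        colMeans(matrix(fit$y[idx], nrow = fit$k))
      }
    ),
    decision_tree = list(
      fit = function(x, y) {
        df <- as.data.frame(as.matrix(x))
        names(df) <- paste0("V", seq_len(ncol(df)))
        df$.y <- factor(y, levels = c(0, 1))
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = 0, xval = 0,
                                                    minsplit = 10))
      },
      predict_prob = function(fit, x) {
        df <- as.data.frame(as.matrix(x))
        names(df) <- paste0("V", seq_len(ncol(df)))
        unname(stats::predict(fit, newdata = df, type = "prob")[, "1"])
      }
    ),
    svm = list(
      fit = function(x, y) {
        x <- as.matrix(x)
        m <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                        scale = FALSE)
        dv <- drop(attr(stats::predict(m, x, decision.values = TRUE),
                        "decision.values"))
        # Platt-style calibration: logistic link on the decision score
        cal <- suppressWarnings(
          stats::glm.fit(cbind(1, dv), y, family = stats::binomial())$coefficients
        )
        list(svm = m, cal = cal)
      },
      predict_prob = function(fit, x) {
        dv <- drop(attr(stats::predict(fit$svm, as.matrix(x),
                                       decision.values = TRUE),
                        "decision.values"))
        unname(stats::plogis(fit$cal[1] + fit$cal[2] * dv))
      }
    ),
    logistic_regression = list(
      fit = function(x, y) {
        co <- suppressWarnings(
          stats::glm.fit(cbind(1, as.matrix(x)), y,
                         family = stats::binomial())$coefficients
        )
        co[is.na(co)] <- 0
        co
      },
      predict_prob = function(fit, x) {
        unname(stats::plogis(drop(cbind(1, as.matrix(x)) %*% fit)))
      }
    ),
    naive_bayes = list(
      fit = function(x, y) gnb_fit(as.matrix(x), y),
      predict_prob = function(fit, x) gnb_predict(fit, as.matrix(x))
    )
  )
  structure(c(list(id = id), fam), class = "model_family")
}

#' @rdname model_family
#' @param ids subset of family identifiers (default: all five).
#' @export
all_model_families <- function(ids = c("knn", "decision_tree", "svm",
                                       "logistic_regression", "naive_bayes")) {
  fams <- lapply(ids, model_family)
  names(fams) <- ids
  fams
}

# Gaussian naive Bayes, vectorized (features treated as conditionally
# independent Gaussians per class; binary 0/1 columns included as-is, as in
# the standard Gaussian variant). Variance smoothing stabilizes
# zero-variance columns.
gnb_fit <- function(x, y, var_smoothing = 1e-9) {
  stopifnot(all(y %in% c(0, 1)))
  mu <- rbind(colMeans(x[y == 0, , drop = FALSE]),
              colMeans(x[y == 1, , drop = FALSE]))
  v <- rbind(apply(x[y == 0, , drop = FALSE], 2, stats::var),
             apply(x[y == 1, , drop = FALSE], 2, stats::var))
  v[!is.finite(v)] <- 0
  eps <- var_smoothing * max(apply(x, 2, stats::var), 1e-12)
  v <- v + eps
  list(mu = mu, v = v, log_prior = log(c(mean(y == 0), mean(y == 1))))
}

gnb_predict <- function(fit, x) {
  ll <- vapply(1:2, function(ci) {
    centered <- sweep(x, 2, fit$mu[ci, ])
    -0.5 * rowSums(sweep(centered^2, 2, fit$v[ci, ], "/") +
                     rep(log(2 * pi * fit$v[ci, ]), each = nrow(x)))
  }, numeric(nrow(x)))
  lp <- sweep(ll, 2, fit$log_prior, "+")
  1 / (1 + exp(lp[, 1] - lp[, 2]))
}
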