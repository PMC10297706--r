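#' Independent two-sample t-test (closed form)
#'
#' Computes the t statistic and two-sided p-value from the closed-form
#' pooled-variance formula (default, assuming equal group variances) or the
#' Welch-Satterthwaite formula. Degenerate inputs: two constant, equal groups
#' give t = 0, p = 1; two constant, unequal groups give p = 0 with a warning.
#'
#' @param x,y numeric vectors (the factor's values in each outcome group),
#'   each of length >= 2, finite.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return list of class `ttest_result`: `t_statistic`, `p_value`, `df`,
#'   `n1` (= length(x)), `n2`, `variant`.
#' @export
ttest_two_sample <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      res <- list(t_statistic = 0, p_value = 1, df = n1 + n2 - 2)
    } else {
      warning("both groups constant with unequal means; p-value set to 0")
      res <- list(t_statistic = sign(m1 - m2) * Inf, p_value = 0,
                  df = n1 + n2 - 2)
    }
  } else if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    t <- (m1 - m2) / se
    res <- list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t <- (m1 - m2) / sqrt(se2)
    res <- list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
  }
  structure(c(res, list(n1 = n1, n2 = n2, variant = variant)),
            class = "ttest_result")
}

#' Rank risk factors by two-sample t-test p-value
#'
#' For every factor column, the values in the positive-outcome group are
#' tested against those in the negative group; factors are ordered by
#' ascending p-value (a lower p-value denotes more importance), with ties
#' broken by ascending factor name. Binary factors are tested as 0/1 numeric
#' columns, through the same test as continuous ones.
#'
#' @param features numeric matrix or data.frame (columns = factors, fully
#'   numeric, no missing values).
#' @param labels binary 0/1 outcome vector (1 = disease).
#' @param variant passed to [ttest_two_sample()].
#' @return a `ranking` data.frame with columns `rank`, `factor`, `score`
#'   (the p-value), `statistic`, and attribute `method = "ttest"`.
#' @export
rank_by_ttest <- function(features, labels, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  features <- as.matrix(features)
  stopifnot(all(labels %in% c(0, 1)), sum(labels == 1) >= 2, sum(labels == 0) >= 2)
  res <- lapply(colnames(features) %||% paste0("V", seq_len(ncol(features))),
                function(nm) {
    tt <- ttest_two_sample(features[labels == 1, nm], features[labels == 0, nm],
                           variant = variant)
    data.frame(factor = nm, score = tt$p_value, statistic = tt$t_statistic)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$score, out$factor), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
  attr(out, "method") <- "ttest"
  class(out) <- c("ranking", class(out))
  out
}
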