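test_that("confusion metrics compute from 2x2 counts", {
  m <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.75)
  expect_equal(unname(m$counts), c(1, 0, 2, 1))  # tp fp tn fn
  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(1, 1, 1))
  inverted <- confusion_metrics(c(1, 0), c(0, 1))
  expect_equal(c(inverted$sensitivity, inverted$specificity, inverted$accuracy),
               c(0, 0, 0))
  expect_warning(nopos <- confusion_metrics(c(0, 0), c(0, 1)), "sensitivity")
  expect_true(is.na(nopos$sensitivity))
})

test_that("ROC/AUC handles perfect, anti-perfect and the 4-point example", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0, 0, 1, 1))$auc, 0)
  # pairs won: (0.9 vs 0.8, 0.1) and (0.7 vs 0.8, 0.1) -> 3 of 4
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
})

test_that("ROC points are monotone from (0,0) to (1,1) and integrate to the AUC", {
  withr::with_seed(11, {
    y <- rbinom(300, 1, 0.3)
    s <- round(rnorm(300) + y, 1)  # rounding forces score ties
  })
  r <- roc_auc(y, s)
  pts <- r$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  trap <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  expect_lt(abs(trap - r$auc), 1e-10)
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  withr::with_seed(12, {
    y <- rbinom(200, 1, 0.4)
    s <- rnorm(200) + 0.8 * y
  })
  mine <- roc_auc(y, s)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-10)
  expect_equal(roc_auc(y, exp(s))$auc, mine, tolerance = 1e-12)
  expect_equal(roc_auc(y, rank(s))$auc, mine, tolerance = 1e-12)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("final evaluation is internally consistent and deterministic", {
  withr::with_seed(13, {
    n <- 400
    y <- rbinom(n, 1, 0.35)
    x <- cbind(a = y + rnorm(n), b = rnorm(n))
    yt <- rbinom(100, 1, 0.35)
    xt <- cbind(a = yt + rnorm(100), b = rnorm(100))
  })
  for (fid in c("logistic_regression", "naive_bayes")) {
    rep <- evaluate_final(model_family(fid), c("a", "b"), x, y, xt, yt,
                          method = "ttest", seed = 5)
    cts <- rep$counts
    expect_equal(rep$sensitivity, cts[["tp"]] / (cts[["tp"]] + cts[["fn"]]))
    expect_equal(rep$specificity, cts[["tn"]] / (cts[["tn"]] + cts[["fp"]]))
    expect_equal(rep$accuracy, (cts[["tp"]] + cts[["tn"]]) / sum(cts))
    trap <- sum(diff(rep$roc$fpr) *
                  (rep$roc$tpr[-1] + rep$roc$tpr[-nrow(rep$roc)]) / 2)
    expect_lt(abs(trap - rep$auc), 1e-10)
    rep2 <- evaluate_final(model_family(fid), c("a", "b"), x, y, xt, yt,
                           method = "ttest", seed = 5)
    expect_identical(rep[names(rep) != "model"], rep2[names(rep2) != "model"])
  }
})

test_that("separable cohorts evaluate perfectly; shuffled labels are null", {
  withr::with_seed(14, {
    y <- rep(c(0, 1), each = 100)
    x <- cbind(sep = y * 4 + runif(200))
    yt <- rep(c(0, 1), each = 40)
    xt <- cbind(sep = yt * 4 + runif(80))
  })
  for (fam in all_model_families()) {
    r <- evaluate_final(fam, "sep", x, y, xt, yt, seed = 2)
    expect_equal(r$auc, 1, tolerance = 1e-9, label = fam$id)
    expect_equal(r$accuracy, 1, tolerance = 1e-9, label = fam$id)
  }
  withr::with_seed(15, {
    n <- 2000
    yperm <- rbinom(n, 1, 0.5)
    xr <- cbind(noise = rnorm(n))
    yt2 <- rbinom(500, 1, 0.5)
    xt2 <- cbind(noise = rnorm(500))
  })
  r0 <- evaluate_final(model_family("logistic_regression"), "noise",
                       xr, yperm, xt2, yt2, seed = 3)
  expect_lt(abs(r0$auc - 0.5), 3 * 0.03)
})
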