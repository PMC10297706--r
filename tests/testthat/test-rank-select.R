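test_that("rank-to-weight conversion gives d-1 down to 0", {
  rk <- data.frame(rank = 1:9, factor = paste0("f", 1:9), score = 1:9 / 10)
  w <- assign_weights(rk, 9)
  expect_equal(unname(w), 8:0)
  expect_equal(w[["f1"]], 8)
  expect_equal(w[["f9"]], 0)
  rk2 <- data.frame(rank = 1:2, factor = c("a", "b"), score = c(0.1, 0.2))
  expect_equal(unname(assign_weights(rk2, 2)), c(1, 0))
  dup <- data.frame(rank = 1:2, factor = c("a", "a"), score = c(0.1, 0.2))
  expect_error(assign_weights(dup, 2), "duplicate")
  # any permutation of factors yields exactly the set {d-1, ..., 0}
  withr::with_seed(1, {
    for (i in 1:5) {
      prm <- rk[sample(9), ]
      prm$rank <- 1:9
      expect_setequal(unname(assign_weights(prm, 9)), 0:8)
    }
  })
})

test_that("cross-validated AUC is deterministic, perfect on a separator, null on noise", {
  withr::with_seed(2, {
    y <- rep(c(0, 1), each = 150)
    sep <- matrix(y + runif(300, 0, 0.3), dimnames = list(NULL, "sep"))
    noise <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
    y_noise <- rep(c(0, 1), 500)
  })
  for (fam in all_model_families(c("logistic_regression", "knn"))) {
    expect_equal(cv_auc(fam, sep, y, folds = 5, seed = 3), 1, tolerance = 1e-9)
  }
  fam <- model_family("logistic_regression")
  a1 <- cv_auc(fam, noise, y_noise, folds = 5, seed = 4)
  expect_identical(a1, cv_auc(fam, noise, y_noise, folds = 5, seed = 4))
  # permutation null: AUC se ~ sqrt(n1+n0+1 / 12 n1 n0) ~ 0.018 at n = 1000
  expect_lt(abs(a1 - 0.5), 3 * 0.02)
})

test_that("greedy elimination follows the prev/curr AUC rule", {
  withr::with_seed(6, {
    n <- 600
    y <- rbinom(n, 1, 0.4)
    x <- cbind(strong = y + rnorm(n, sd = 0.7),
               medium = y + rnorm(n, sd = 2),
               junk = rnorm(n))
  })
  fam <- model_family("logistic_regression")
  rk <- rank_by_ttest(x, y)
  w0 <- assign_weights(rk, 3)
  gs <- greedy_select(fam, rk, w0, x, y, folds = 5, seed = 7)
  # first ranked factor is always kept (prev_AUC starts at 0)
  expect_identical(gs$trace$decision[1], "kept")
  expect_identical(gs$trace$prev_auc[1], 0)
  # accepted AUCs strictly increase along the trace
  kept <- gs$trace[gs$trace$decision == "kept", ]
  expect_true(all(diff(c(0, kept$curr_auc)) > 0))
  # weights are the initial value or exactly zero
  expect_true(all(gs$weights == w0[names(gs$weights)] | gs$weights == 0))
  # removed factors end at zero
  removed <- gs$trace$factor[gs$trace$decision == "removed"]
  expect_true(all(gs$weights[removed] == 0))
})

test_that("a pure-noise factor is usually eliminated", {
  hits <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      n <- 500
      y <- rbinom(n, 1, 0.5)
      x <- cbind(signal = y + rnorm(n, sd = 0.8), junk = rnorm(n))
    })
    rk <- data.frame(rank = 1:2, factor = c("signal", "junk"), score = c(0, 1))
    fam <- model_family("logistic_regression")
    gs <- greedy_select(fam, rk, assign_weights(rk, 2), x, y,
                        folds = 5, seed = seed)
    gs$weights[["junk"]] == 0
  }, TRUE)
  expect_gt(sum(hits), 5)
})

test_that("ensemble weights average family x repeat grids with name-ordered ties", {
  w1 <- c(a = 8, b = 0)
  w2 <- c(b = 8, a = 0)
  ens <- ensemble_weights(list(w1, w2))
  expect_equal(unname(ens$weights), c(4, 4))
  expect_identical(ens$ranking$factor, c("a", "b"))  # tie broken by name
  # identical vectors: ensemble equals the single vector
  same <- ensemble_weights(list(w1, w1, w1))
  expect_equal(same$weights[c("a", "b")], w1)
  # averaging identical repeats is idempotent
  expect_equal(ensemble_weights(list(w1, w2, w1, w2))$weights,
               ens$weights)
  expect_error(ensemble_weights(list(w1, c(a = 1, c = 2))), "mismatched")
})

test_that("best prefix finds the smallest maximal-AUC prefix", {
  rk1 <- data.frame(rank = 1, factor = "only", score = 0)
  withr::with_seed(8, {
    y <- rep(c(0, 1), each = 100)
    x1 <- matrix(y + rnorm(200, sd = 0.5), dimnames = list(NULL, "only"))
  })
  fam <- model_family("logistic_regression")
  bp1 <- best_prefix(fam, rk1, x1, y, folds = 4, seed = 1)
  expect_identical(bp1$subset, "only")
  # one informative factor ranked first among noise: prefix {top-1} usually wins
  hits <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n <- 2000
      y <- rbinom(n, 1, 0.5)
      x <- cbind(signal = y + rnorm(n, sd = 0.6),
                 n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    })
    rk <- data.frame(rank = 1:4, factor = colnames(x), score = 1:4)
    bp <- best_prefix(fam, rk, x, y, folds = 5, seed = seed)
    identical(bp$subset, "signal")
  }, TRUE)
  expect_gt(sum(hits), 10)
})

test_that("complementary informative factors extend the winning prefix", {
  hits <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      n <- 800
      f1 <- rnorm(n); f2 <- rnorm(n)
      y <- rbinom(n, 1, plogis(1.2 * f1 + 1.2 * f2))
      x <- cbind(f1 = f1, f2 = f2)
    })
    rk <- data.frame(rank = 1:2, factor = c("f1", "f2"), score = 1:2)
    bp <- best_prefix(model_family("logistic_regression"), rk, x, y,
                      folds = 5, seed = seed)
    length(bp$subset) == 2
  }, TRUE)
  expect_gt(sum(hits), 5)
})
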