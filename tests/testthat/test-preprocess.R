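test_that("stratified split preserves class proportions exactly", {
  co <- make_cohort(data.frame(x = rnorm(100)), rep(c(0, 1), each = 50),
                    c(x = "continuous"))
  sp <- split_cohort(co, 0.2, seed = 1)
  expect_equal(nrow(sp$test$data), 20)
  expect_equal(sum(sp$test$labels), 10)
  # disjoint, exhaustive
  expect_equal(nrow(sp$train$data) + nrow(sp$test$data), 100)
  expect_identical(sp, split_cohort(co, 0.2, seed = 1))
  expect_false(identical(sp$test$data, split_cohort(co, 0.2, seed = 2)$test$data))
})

test_that("an 80/20 split of 3,990 subjects holds out 798", {
  co <- generate_cohort(default_dr_specs(), 3990,
                        solve_intercept(default_dr_specs(), 0.215), seed = 1)
  sp <- split_cohort(co, 0.2, seed = 1)
  expect_equal(nrow(sp$test$data), 798)
})

test_that("imputation and normalization parameters come from training values only", {
  co <- make_cohort(data.frame(num = c(1, 2, 3, 4, NA), bin = c(0, 0, 0, 1, NA)),
                    c(0, 1, 0, 1, 1), c(num = "continuous", bin = "binary"))
  pm <- fit_preprocess(co)
  expect_equal(pm$columns$num$impute, 2.5)   # median of 1..4
  expect_equal(pm$columns$num$center, 2.5)   # mean of 1..4
  expect_equal(pm$columns$bin$impute, 0)     # mode of 0,0,0,1
  out <- apply_preprocess(pm, co)
  expect_false(anyNA(out$data))
  expect_equal(out$data$bin[5], 0)           # missing binary filled with mode
  # imputed then standardized with training center/scale
  expect_equal(out$data$num[5], (2.5 - 2.5) / pm$columns$num$scale)
})

test_that("zero-variance continuous column degrades to scale 1 with a warning", {
  co <- make_cohort(data.frame(num = c(5, 5, 5)), c(0, 1, 1),
                    c(num = "continuous"))
  expect_warning(pm <- fit_preprocess(co), "zero variance")
  expect_equal(pm$columns$num$center, 5)
  expect_equal(pm$columns$num$scale, 1)
})

test_that("applying the model to its own training data standardizes it", {
  co <- generate_cohort(default_dr_specs(), 800, -1, missing_rate = 0.02, seed = 4)
  pm <- fit_preprocess(co)
  out <- apply_preprocess(pm, co)
  for (nm in c("age", "body_mass_index", "glycosylated_hemoglobin")) {
    expect_lt(abs(mean(out$data[[nm]])), 0.05)
    expect_lt(abs(sd(out$data[[nm]]) - 1), 0.05)
  }
  # applying the same fitted model twice to the same table gives the same result
  expect_identical(out$data, apply_preprocess(pm, co)$data)
})

test_that("unseen binary category fails loudly, naming the column", {
  tr <- make_cohort(data.frame(bin = c(0, 1, 0, 1)), c(0, 1, 0, 1),
                    c(bin = "binary"))
  pm <- fit_preprocess(tr)
  bad <- make_cohort(data.frame(bin = c(0, 2)), c(0, 1), c(bin = "binary"))
  expect_error(apply_preprocess(pm, bad), "bin")
})

test_that("the preprocessing model never sees test rows", {
  co <- generate_cohort(default_dr_specs(), 600, -1, missing_rate = 0.05, seed = 6)
  sp <- split_cohort(co, 0.25, seed = 1)
  pm1 <- fit_preprocess(sp$train)
  mutated <- sp
  mutated$test$data[] <- lapply(mutated$test$data, function(x) x * 100)
  expect_identical(pm1, fit_preprocess(mutated$train))
})

test_that("preprocess model round-trips through its JSON sidecar", {
  co <- generate_cohort(default_dr_specs(), 300, -1, missing_rate = 0.05, seed = 8)
  pm <- fit_preprocess(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess(pm, path)
  back <- read_preprocess(path)
  out1 <- apply_preprocess(pm, co)$data
  out2 <- apply_preprocess(back, co)$data
  expect_equal(out1, out2, tolerance = 1e-12)
})

test_that("SMOTE interpolates on segments between minority neighbours", {
  # two identical minority points: every synthetic point equals them
  x <- rbind(matrix(rnorm(20), 10), matrix(1, 2, 2))
  y <- c(rep(0, 10), 1, 1)
  out <- suppressWarnings(smote(x, y, k = 5, seed = 1))
  expect_true(all(out$x[out$synthetic, ] == 1))
  # minority (0,0) and (1,1), k = 1: synthetic points on the diagonal segment
  x2 <- rbind(matrix(rnorm(40, 5), 20), c(0, 0), c(1, 1))
  y2 <- c(rep(0, 20), 1, 1)
  out2 <- smote(x2, y2, k = 1, seed = 2)
  synth <- out2$x[out2$synthetic, , drop = FALSE]
  expect_equal(synth[, 1], synth[, 2])
  expect_true(all(synth >= 0 & synth <= 1))
})

test_that("SMOTE balances classes and leaves originals untouched", {
  f <- make_classification(n = 400, seed = 3)
  y <- c(rep(0, 300), rep(1, 100))
  out <- smote(f$x, y, k = 5, seed = 4)
  expect_equal(as.vector(table(out$y)), c(300, 300))
  expect_equal(out$x[1:400, ], f$x, ignore_attr = TRUE)
  expect_identical(out, smote(f$x, y, k = 5, seed = 4))
  # minority count <= k falls back with a warning
  y_tiny <- c(rep(0, 397), rep(1, 3))
  expect_warning(smote(f$x, y_tiny, k = 5, seed = 1), "k = 2")
})

test_that("every synthetic SMOTE row is a convex combination of two minority rows", {
  f <- make_classification(n = 130, n_noise = 1, seed = 5)
  y <- c(rep(0, 100), rep(1, 30))
  out <- smote(f$x, y, k = 3, seed = 6)
  minority <- f$x[y == 1, , drop = FALSE]
  synth <- out$x[out$synthetic, , drop = FALSE]
  for (r in seq_len(nrow(synth))) {
    s <- synth[r, ]
    ok <- FALSE
    for (i in seq_len(nrow(minority))) {
      diff <- minority[i, ] - s
      for (j in seq_len(nrow(minority))[-i]) {
        seg <- minority[i, ] - minority[j, ]
        # s = x_i + u (x_j - x_i): solve u on the first non-degenerate axis
        ax <- which(abs(seg) > 1e-12)[1]
        if (is.na(ax)) next
        u <- diff[ax] / seg[ax]
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(s - (minority[i, ] - u * seg))) < 1e-8) {
          ok <- TRUE; break
        }
      }
      if (ok) break
    }
    expect_true(ok, label = sprintf("synthetic row %d lies on a minority segment", r))
  }
})
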