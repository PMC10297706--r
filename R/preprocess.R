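#' Stratified train/test split of a cohort
#'
#' Rows are assigned to the test partition per class: each class contributes
#' `round(n_class * test_fraction)` rows, so class proportions are preserved
#' under the severe imbalance typical of retinopathy cohorts.
#'
#' @param cohort a `cohort`.
#' @param test_fraction proportion in (0,1); default 0.2.
#' @param seed integer seed.
#' @return list with `train` and `test` (both `cohort` objects sharing the
#'   input specs), `test_fraction`, and `seed`.
#' @export
split_cohort <- function(cohort, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- cohort$labels
  if (any(table(y) < 2L)) stop("each class needs at least 2 members to split")
  test_idx <- local_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      sample(ix, round(length(ix) * test_fraction))
    }), use.names = FALSE)
  })
  slice <- function(idx) {
    structure(list(data = cohort$data[idx, , drop = FALSE],
                   labels = cohort$labels[idx], specs = cohort$specs,
                   seed = cohort$seed),
              class = "cohort")
  }
  list(train = slice(setdiff(seq_along(y), test_idx)),
       test = slice(sort(test_idx)),
       test_fraction = test_fraction, seed = as.integer(seed))
}

#' Fit the preprocessing model on a training partition
#'
#' Computes, from non-missing training values only: the imputation value per
#' column (mode for binary factors, median for continuous), the z-score
#' parameters (mean, standard deviation) per continuous column, and the
#' category map for binary columns (sorted unique values mapped to 0/1).
#' Binary ties in the mode are broken toward the smaller encoded value. A
#' continuous column with zero variance gets scale 1 with a warning.
#'
#' @param train a `cohort` (training rows only — the model must never see
#'   test rows).
#' @return an object of class `preprocess_model`.
#' @export
fit_preprocess <- function(train) {
  stopifnot(nrow(train$data) > 0)
  kinds <- factor_kinds(train)
  cols <- lapply(names(kinds), function(nm) {
    x <- train$data[[nm]]
    obs <- x[!is.na(x)]
    if (length(obs) == 0) stop("column '", nm, "' has no observed values")
    if (kinds[[nm]] == "binary") {
      lv <- sort(unique(obs))
      if (length(lv) > 2) stop("binary column '", nm, "' has >2 categories")
      enc <- match(obs, lv) - 1L
      tab <- table(enc)
      mode_val <- as.integer(names(tab)[which.max(tab)])  # which.max: first max, i.e. smaller value on ties
      list(kind = "binary", levels = lv, impute = mode_val)
    } else {
      ctr <- mean(obs)
      scl <- stats::sd(obs)
      if (!is.finite(scl) || scl == 0) {
        warning("continuous column '", nm, "' has zero variance; scale set to 1")
        scl <- 1
      }
      list(kind = "continuous", impute = stats::median(obs),
           center = ctr, scale = scl)
    }
  })
  names(cols) <- names(kinds)
  structure(list(columns = cols), class = "preprocess_model")
}

#' Apply a fitted preprocessing model to a cohort
#'
#' Binary columns are mapped to \{0,1\} via the stored category order and
#' missing cells filled with the stored mode; continuous columns are
#' median-imputed (imputation precedes standardization) then standardized
#' with the training-derived center and scale. Test data never refits. An
#' unseen category in a binary column is an error naming the column.
#'
#' @param model a `preprocess_model`.
#' @param cohort a `cohort` with the same columns.
#' @return the cohort with fully numeric, complete `data`.
#' @export
apply_preprocess <- function(model, cohort) {
  stopifnot(inherits(model, "preprocess_model"),
            identical(names(cohort$data), names(model$columns)))
  dat <- cohort$data
  for (nm in names(model$columns)) {
    cm <- model$columns[[nm]]
    x <- dat[[nm]]
    if (cm$kind == "binary") {
      obs <- !is.na(x)
      if (any(!(x[obs] %in% cm$levels))) {
        stop("unseen category in binary column '", nm, "'")
      }
      enc <- rep(NA_integer_, length(x))
      enc[obs] <- match(x[obs], cm$levels) - 1L
      enc[!obs] <- cm$impute
      dat[[nm]] <- as.numeric(enc)
    } else {
      x[is.na(x)] <- cm$impute
      dat[[nm]] <- (x - cm$center) / cm$scale
    }
  }
  out <- cohort
  out$data <- dat
  out
}

#' Serialize / restore a preprocessing model (JSON sidecar)
#'
#' @param model a `preprocess_model`.
#' @param path JSON file path.
#' @export
write_preprocess <- function(model, path) {
  jsonlite::write_json(model$columns, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess
#' @export
read_preprocess <- function(path) {
  cols <- jsonlite::read_json(path, simplifyVector = TRUE)
  cols <- lapply(cols, function(cm) {
    if (identical(cm$kind, "binary")) cm$levels <- as.numeric(cm$levels)
    cm
  })
  structure(list(columns = cols), class = "preprocess_model")
}

#' SMOTE: synthetic minority oversampling to class balance
#'
#' Each synthetic minority row is `x + u * (x_nn - x)` with `u ~ Uniform(0,1)`,
#' `x` a minority row and `x_nn` one of its `k` nearest minority neighbours
#' under Euclidean distance. Enough synthetic rows are generated to equalize
#' the class counts; base rows are cycled in order so the synthetic count per
#' minority row differs by at most one. If the minority class has at most `k`
#' members, `k` is reduced to (minority count - 1) with a warning.
#'
#' @param x numeric matrix or data.frame of features (no missing values —
#'   i.e. post-preprocessing).
#' @param y binary 0/1 label vector.
#' @param k number of nearest neighbours (default 5, the technique's
#'   canonical setting).
#' @param seed integer seed.
#' @return list with `x` (matrix: original rows then synthetic minority
#'   rows), `y`, and `synthetic` (logical marker per row).
#' @export
smote <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(!anyNA(x), is.numeric(x), all(y %in% c(0, 1)), k >= 1)
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min < 2) stop("minority class needs at least 2 members for SMOTE")
  n_new <- n_maj - n_min
  if (n_new == 0) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }
  if (n_min <= k) {
    warning("minority count <= k; using k = ", n_min - 1L)
    k <- n_min - 1L
  }
  min_idx <- which(y == minority)
  xm <- x[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  # k nearest minority neighbours per minority row (ties by index order)
  nn <- matrix(vapply(seq_len(n_min), function(i) order(d[i, ])[seq_len(k)],
                      integer(k)),
               nrow = n_min, byrow = TRUE)
  local_seed(seed, {
    base <- rep(seq_len(n_min), length.out = n_new)
    pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    synth <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    list(x = rbind(x, synth),
         y = c(y, rep(minority, n_new)),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)))
  })
}
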