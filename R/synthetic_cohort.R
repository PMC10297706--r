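#' Describe one risk factor for the synthetic cohort generator
#'
#' A factor is either `binary` (Bernoulli with success rate `rate`) or
#' `continuous` (Gaussian with `mean` and `sd` in natural clinical units,
#' optionally truncated below at `lower`). Its association with the outcome is
#' a log-odds coefficient `effect` applied to the *standardized* factor value,
#' so effects are comparable across factors regardless of units.
#'
#' @param name column name (snake_case).
#' @param kind `"binary"` or `"continuous"`.
#' @param rate Bernoulli rate in (0,1); binary factors only.
#' @param mean,sd Gaussian parameters in natural units; continuous only; `sd > 0`.
#' @param effect log-odds coefficient on the standardized value.
#' @param lower lower truncation bound for continuous factors (default none).
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(name, kind = c("continuous", "binary"),
                        rate = NULL, mean = NULL, sd = NULL,
                        effect = 0, lower = -Inf) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), nchar(name) > 0, is.numeric(effect))
  if (kind == "binary") {
    stopifnot(is.numeric(rate), rate > 0, rate < 1)
  } else {
    stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  }
  structure(list(name = name, kind = kind, rate = rate, mean = mean,
                 sd = sd, effect = effect, lower = lower),
            class = "factor_spec")
}

#' Default risk-factor specifications for a diabetic retinopathy cohort
#'
#' Nine factors: three binary (gender, history of hypertension, insulin
#' treatment) and six continuous (age, body mass index, systolic blood
#' pressure, diabetes duration, fasting plasma glucose, glycosylated
#' hemoglobin). Default planted effects are large for systolic blood
#' pressure, glycosylated hemoglobin and diabetes duration, moderate for
#' history of hypertension, insulin treatment and fasting plasma glucose,
#' small for body mass index and gender, and exactly zero for age. Ages are
#' truncated at 40, matching a cohort restricted to adults aged 40 and older.
#'
#' @param effects optional named numeric vector overriding default effects,
#'   e.g. `c(age = 0.5)`; names must be factor names.
#' @return list of nine [factor_spec()] objects.
#' @export
default_dr_specs <- function(effects = NULL) {
  specs <- list(
    factor_spec("age", "continuous", mean = 58, sd = 10, effect = 0, lower = 40),
    factor_spec("gender", "binary", rate = 0.5, effect = 0.10),
    factor_spec("body_mass_index", "continuous", mean = 25, sd = 4, effect = 0.10),
    factor_spec("systolic_blood_pressure", "continuous", mean = 132, sd = 18,
                effect = 0.80),
    factor_spec("history_of_hypertension", "binary", rate = 0.35, effect = 0.35),
    factor_spec("diabetes_duration", "continuous", mean = 8, sd = 6,
                effect = 0.70, lower = 0),
    factor_spec("insulin_treatment", "binary", rate = 0.20, effect = 0.35),
    factor_spec("fasting_plasma_glucose", "continuous", mean = 145, sd = 45,
                effect = 0.35),
    factor_spec("glycosylated_hemoglobin", "continuous", mean = 8.2, sd = 1.8,
                effect = 0.80)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (!is.null(effects)) {
    stopifnot(!is.null(names(effects)), all(names(effects) %in% names(specs)))
    for (nm in names(effects)) specs[[nm]]$effect <- effects[[nm]]
  }
  specs
}

# Standardize a factor column using the spec's population parameters:
# (x - mean)/sd for continuous, (x - rate)/sqrt(rate(1-rate)) for binary.
standardize_by_spec <- function(x, spec) {
  if (spec$kind == "binary") {
    (x - spec$rate) / sqrt(spec$rate * (1 - spec$rate))
  } else {
    (x - spec$mean) / spec$sd
  }
}

# Truncated-normal draw by iterated redraw of rejected values.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

draw_factor <- function(n, spec) {
  if (spec$kind == "binary") {
    stats::rbinom(n, 1L, spec$rate)
  } else {
    rtruncnorm_lower(n, spec$mean, spec$sd, spec$lower)
  }
}

#' Solve the logistic intercept for a target outcome prevalence
#'
#' Given factor specifications with planted effects, finds the intercept `b`
#' such that the expected prevalence `E[plogis(b + sum_j effect_j z_j)]`
#' equals `prevalence`, by Monte Carlo integration over a fixed sample of
#' standardized factor draws and root finding.
#'
#' @param specs list of [factor_spec()].
#' @param prevalence target positive-class rate in (0,1).
#' @param n_mc Monte Carlo sample size.
#' @param seed seed for the Monte Carlo draw (fixed default makes the solved
#'   intercept a deterministic function of `specs` and `prevalence`).
#' @return the intercept, a single numeric.
#' @export
solve_intercept <- function(specs, prevalence, n_mc = 100000L, seed = 20260101L) {
  stopifnot(prevalence > 0, prevalence < 1)
  eta <- local_seed(seed, {
    z <- vapply(specs, function(sp) {
      standardize_by_spec(draw_factor(n_mc, sp), sp)
    }, numeric(n_mc))
    drop(z %*% vapply(specs, `[[`, 0, "effect"))
  })
  f <- function(b) mean(stats::plogis(b + eta)) - prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic subject-level cohort with planted logistic effects
#'
#' Factor values are drawn independently per specification; the binary
#' outcome for subject `i` is Bernoulli with success probability
#' `plogis(intercept + sum_j effect_j * z_ij)` where `z_ij` is the factor
#' value standardized by its specification parameters. After labels are
#' drawn, each factor cell is set missing independently with probability
#' `missing_rate` (missing completely at random). Identical arguments
#' reproduce the identical cohort.
#'
#' @param specs list of [factor_spec()]; default [default_dr_specs()].
#' @param n number of subjects (>= 10).
#' @param intercept logistic intercept; use [solve_intercept()] to target a
#'   prevalence.
#' @param missing_rate per-cell missingness probability in [0, 1).
#' @param seed integer seed.
#' @param max_redraws label redraws attempted if a single-class label vector
#'   is drawn before failing.
#' @return an object of class `cohort`: list with `data` (data.frame of
#'   factor columns, `NA` for missing), `labels` (integer 0/1, 1 = disease),
#'   `specs`, and `seed`.
#' @export
generate_cohort <- function(specs = default_dr_specs(), n, intercept = 0,
                            missing_rate = 0, seed = 1L, max_redraws = 5L) {
  stopifnot(length(specs) >= 2, n >= 10, missing_rate >= 0, missing_rate < 1)
  local_seed(seed, {
    dat <- lapply(specs, draw_factor, n = n)
    z <- mapply(standardize_by_spec, dat, specs)
    eta <- intercept + drop(z %*% vapply(specs, `[[`, 0, "effect"))
    p <- stats::plogis(eta)
    labels <- stats::rbinom(n, 1L, p)
    tries <- 0L
    while (length(unique(labels)) < 2L && tries < max_redraws) {
      labels <- stats::rbinom(n, 1L, p)
      tries <- tries + 1L
    }
    if (length(unique(labels)) < 2L) {
      stop("degenerate cohort: labels contain a single class after ",
           max_redraws, " redraws")
    }
    dat <- as.data.frame(dat, optional = TRUE)
    names(dat) <- vapply(specs, `[[`, "", "name")
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(n * length(specs)) < missing_rate,
                     nrow = n)
      dat[mask] <- NA
    }
    structure(list(data = dat, labels = as.integer(labels), specs = specs,
                   seed = as.integer(seed)),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d factors, %d positive (%.1f%%), %d missing cells\n",
              nrow(x$data), ncol(x$data), sum(x$labels),
              100 * mean(x$labels), sum(is.na(x$data))))
  invisible(x)
}

#' Write a cohort to CSV
#'
#' Header row with snake_case factor names plus a final `dr_status` column in
#' \{0,1\}; missing cells are written as empty fields. This schema is the
#' pipeline-wide tabular input contract.
#'
#' @param cohort a `cohort`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  out <- cbind(cohort$data, dr_status = cohort$labels)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Expects the schema produced by [write_cohort()]: factor columns then a
#' binary `dr_status` column; empty fields become missing values. Factor
#' kinds are taken from `specs` when given, otherwise inferred (columns whose
#' non-missing values are all in \{0,1\} are binary).
#'
#' @param path CSV path.
#' @param specs optional list of [factor_spec()] matching the file's columns.
#' @return a `cohort`.
#' @export
read_cohort <- function(path, specs = NULL) {
  df <- utils::read.csv(path, na.strings = "")
  stopifnot("dr_status" %in% names(df))
  labels <- as.integer(df$dr_status)
  stopifnot(all(labels %in% c(0L, 1L)))
  dat <- df[setdiff(names(df), "dr_status")]
  if (is.null(specs)) {
    specs <- lapply(names(dat), function(nm) {
      x <- dat[[nm]][!is.na(dat[[nm]])]
      if (all(x %in% c(0, 1))) {
        factor_spec(nm, "binary", rate = max(min(mean(x), 0.99), 0.01))
      } else {
        factor_spec(nm, "continuous", mean = mean(x), sd = max(stats::sd(x), 1e-8))
      }
    })
    names(specs) <- names(dat)
  } else {
    stopifnot(identical(names(dat), unname(vapply(specs, `[[`, "", "name"))))
  }
  structure(list(data = dat, labels = labels, specs = specs, seed = NA_integer_),
            class = "cohort")
}

# Factor kind lookup: named character vector c(name = "binary"/"continuous").
factor_kinds <- function(cohort) {
  vapply(cohort$specs, `[[`, "", "kind")
}
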