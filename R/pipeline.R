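#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis with defaults matching the
#' study design: an 80/20 stratified split, SMOTE to class balance on the
#' training partition, 5-fold cross-validated AUC, three repeats with derived
#' seeds, both ranking methods, and all five classifier families.
#'
#' Cost knobs: `rank_train_cap` bounds the rows used for model fitting inside
#' the greedy scan and prefix search, and `shap_train_cap` bounds the rows
#' used to retrain subset models for the Shapley value function (stratified
#' subsamples — ranking depends on score order, not absolute AUC precision).
#' `shap_eval_cap` caps the held-out instances the local Shapley values are
#' averaged over.
#'
#' @param input optional path to a cohort CSV (see [read_cohort()]); when
#'   `NULL` a synthetic cohort is generated.
#' @param specs factor specifications for the generator.
#' @param n cohort size for the generator.
#' @param prevalence target positive rate for the generator (intercept is
#'   solved numerically).
#' @param missing_rate generator per-cell missingness.
#' @param seed single run seed; all stage seeds derive from it.
#' @param test_fraction held-out proportion.
#' @param cv_folds stratified folds for [cv_auc()].
#' @param repeats number of independent repeats averaged into the ensemble.
#' @param methods ranking methods to run, subset of `c("ttest", "shap")`.
#' @param families classifier family identifiers (see [model_family()]).
#' @param ttest_variant `"pooled"` or `"welch"`.
#' @param smote_k SMOTE neighbour count.
#' @param shap_mode `"auto"`, `"exact"` or `"permutation"`.
#' @param n_permutations Monte Carlo orderings in permutation mode.
#' @param rank_train_cap,shap_train_cap,shap_eval_cap cost caps (rows).
#' @param do_evaluate run the best-prefix search and final held-out
#'   evaluation (disable to compute rankings only).
#' @param output_dir optional directory for the CSV outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, specs = default_dr_specs(), n = 3990L,
                       prevalence = 857 / 3990, missing_rate = 0.05,
                       seed = 1L, test_fraction = 0.2, cv_folds = 5L,
                       repeats = 3L, methods = c("ttest", "shap"),
                       families = c("knn", "decision_tree", "svm",
                                    "logistic_regression", "naive_bayes"),
                       ttest_variant = "pooled", smote_k = 5L,
                       shap_mode = "permutation", n_permutations = 16L,
                       rank_train_cap = 1000L, shap_train_cap = 500L,
                       shap_eval_cap = 200L, do_evaluate = TRUE,
                       output_dir = NULL) {
  stopifnot(all(methods %in% c("ttest", "shap")), length(methods) >= 1,
            repeats >= 1, cv_folds >= 2)
  structure(list(input = input, specs = specs, n = as.integer(n),
                 prevalence = prevalence, missing_rate = missing_rate,
                 seed = as.integer(seed), test_fraction = test_fraction,
                 cv_folds = as.integer(cv_folds), repeats = as.integer(repeats),
                 methods = methods, families = families,
                 ttest_variant = ttest_variant, smote_k = as.integer(smote_k),
                 shap_mode = shap_mode,
                 n_permutations = as.integer(n_permutations),
                 rank_train_cap = as.integer(rank_train_cap),
                 shap_train_cap = as.integer(shap_train_cap),
                 shap_eval_cap = as.integer(shap_eval_cap),
                 do_evaluate = isTRUE(do_evaluate), output_dir = output_dir),
            class = "run_config")
}

#' Run the full risk-factor ranking pipeline
#'
#' Executes: generate/load cohort -> stratified split -> preprocessing fitted
#' on the training partition -> SMOTE to class balance -> per-method ranking
#' (t-test p-values; per-family retrain-based Shapley importances) -> rank-to-
#' weight conversion (d - r) -> greedy cross-validated-AUC elimination per
#' family -> repeat averaging and five-family ensemble -> best ranking prefix
#' -> final held-out evaluation per family. Each repeat uses a fresh split
#' and fresh SMOTE under a derived seed; the first repeat's partitions host
#' the best-prefix search and the final evaluation.
#'
#' Identical configurations (including the seed) produce byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return a `retinorank_run` list: `cohort`, `rankings` (initial, long
#'   data.frame), `weights` (post-greedy, long), `traces` (long),
#'   `ensemble` (per method: `weights`, `ranking`), `model_tables` (per
#'   method: rank x family data.frame of the per-family final rankings),
#'   `prefix` (per method per family: best subset + AUC), `metrics` (per
#'   method data.frame), `roc` (long data.frame), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    intercept <- solve_intercept(config$specs, config$prevalence)
    generate_cohort(config$specs, config$n, intercept,
                    missing_rate = config$missing_rate,
                    seed = derive_seed(config$seed, "cohort"))
  }
  families <- all_model_families(config$families)
  d <- ncol(cohort$data)
  facs <- names(cohort$data)

  rankings <- list(); weights <- list(); traces <- list()
  rep1 <- NULL
  for (rep_i in seq_len(config$repeats)) {
    srep <- derive_seed(config$seed, "repeat", rep_i)
    sp <- split_cohort(cohort, config$test_fraction,
                       seed = derive_seed(srep, "split"))
    pm <- fit_preprocess(sp$train)
    tr <- apply_preprocess(pm, sp$train)
    te <- apply_preprocess(pm, sp$test)
    sm <- smote(tr$data, tr$labels, k = config$smote_k,
                seed = derive_seed(srep, "smote"))
    x_all <- sm$x; y_all <- sm$y
    idx_rank <- stratified_cap(y_all, config$rank_train_cap,
                               derive_seed(srep, "cap-rank"))
    x_rank <- x_all[idx_rank, , drop = FALSE]; y_rank <- y_all[idx_rank]
    if (rep_i == 1L) {
      rep1 <- list(x_full = x_all, y_full = y_all, x_rank = x_rank,
                   y_rank = y_rank, test = te)
    }

    # ranking per method (t-test shared across families; Shapley per family)
    rank_tt <- if ("ttest" %in% config$methods) {
      rank_by_ttest(x_all, y_all, variant = config$ttest_variant)
    }
    shap_ranks <- NULL
    if ("shap" %in% config$methods) {
      idx_shap <- stratified_cap(y_all, config$shap_train_cap,
                                 derive_seed(srep, "cap-shap"))
      n_eval <- min(nrow(te$data), config$shap_eval_cap)
      eval_idx <- local_seed(derive_seed(srep, "shap-eval"),
                             sort(sample.int(nrow(te$data), n_eval)))
      x_eval <- as.matrix(te$data)[eval_idx, , drop = FALSE]
      shap_ranks <- lapply(families, function(fam) {
        att <- shapley_attribution(x_all[idx_shap, , drop = FALSE],
                                   y_all[idx_shap], fam, x_eval,
                                   mode = config$shap_mode,
                                   n_permutations = config$n_permutations,
                                   seed = derive_seed(srep, paste0("shap-", fam$id)))
        rank_by_shapley(att)
      })
    }

    for (method in config$methods) {
      for (fam in families) {
        rk <- if (method == "ttest") rank_tt else shap_ranks[[fam$id]]
        w0 <- assign_weights(rk, d)
        gs <- greedy_select(fam, rk, w0, x_rank, y_rank,
                            folds = config$cv_folds,
                            seed = derive_seed(srep, paste0("greedy-", method,
                                                            "-", fam$id)))
        key <- paste(method, fam$id, rep_i, sep = ".")
        rankings[[key]] <- data.frame(method = method, model = fam$id,
                                      repeat_idx = rep_i,
                                      rk[, c("rank", "factor", "score")])
        weights[[key]] <- data.frame(method = method, model = fam$id,
                                     repeat_idx = rep_i,
                                     factor = names(gs$weights),
                                     initial_weight = unname(w0[names(gs$weights)]),
                                     weight = unname(gs$weights))
        traces[[key]] <- data.frame(method = method, model = fam$id,
                                    repeat_idx = rep_i, gs$trace)
      }
    }
  }
  rankings <- do.call(rbind, c(rankings, list(make.row.names = FALSE)))
  weights_df <- do.call(rbind, c(weights, list(make.row.names = FALSE)))
  traces <- do.call(rbind, c(traces, list(make.row.names = FALSE)))

  ensemble <- lapply(stats::setNames(config$methods, config$methods),
                     function(method) {
    wl <- lapply(split(weights_df[weights_df$method == method, ],
                       interaction(weights_df$model[weights_df$method == method],
                                   weights_df$repeat_idx[weights_df$method == method],
                                   drop = TRUE)),
                 function(df) stats::setNames(df$weight, df$factor))
    ensemble_weights(unname(wl))
  })

  # Tables-1/2-shaped per-family final rankings: mean post-greedy weight over
  # repeats, descending, ties by factor name.
  model_tables <- lapply(stats::setNames(config$methods, config$methods),
                         function(method) {
    cols <- lapply(config$families, function(fid) {
      df <- weights_df[weights_df$method == method & weights_df$model == fid, ]
      mw <- tapply(df$weight, df$factor, mean)
      names(mw)[order(-mw, names(mw))]
    })
    out <- data.frame(rank = seq_len(d))
    for (i in seq_along(config$families)) out[[config$families[i]]] <- cols[[i]]
    out
  })

  prefix <- NULL; metrics <- NULL; roc <- NULL
  if (config$do_evaluate) {
    prefix <- lapply(stats::setNames(config$methods, config$methods),
                     function(method) {
      lapply(families, function(fam) {
        best_prefix(fam, ensemble[[method]]$ranking, rep1$x_rank, rep1$y_rank,
                    folds = config$cv_folds,
                    seed = derive_seed(config$seed,
                                       paste0("prefix-", method, "-", fam$id)))
      })
    })
    ev <- lapply(stats::setNames(config$methods, config$methods),
                 function(method) {
      reps <- lapply(families, function(fam) {
        evaluate_final(fam, prefix[[method]][[fam$id]]$subset,
                       rep1$x_full, rep1$y_full,
                       rep1$test$data, rep1$test$labels, method = method,
                       seed = derive_seed(config$seed,
                                          paste0("eval-", method, "-", fam$id)))
      })
      list(
        metrics = do.call(rbind, lapply(reps, function(r) {
          data.frame(method = method, model = r$model,
                     sensitivity = r$sensitivity, specificity = r$specificity,
                     auc = r$auc, accuracy = r$accuracy,
                     n_factors = length(r$subset),
                     subset = paste(r$subset, collapse = "+"))
        })),
        roc = do.call(rbind, lapply(reps, function(r) {
          data.frame(method = method, model = r$model, r$roc)
        })),
        reports = reps
      )
    })
    metrics <- do.call(rbind, c(lapply(ev, `[[`, "metrics"),
                                list(make.row.names = FALSE)))
    roc <- do.call(rbind, c(lapply(ev, `[[`, "roc"),
                            list(make.row.names = FALSE)))
  }

  run <- structure(list(cohort = cohort, rankings = rankings,
                        weights = weights_df, traces = traces,
                        ensemble = ensemble, model_tables = model_tables,
                        prefix = prefix, metrics = metrics, roc = roc,
                        config = config),
                   class = "retinorank_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' Write a pipeline run's tables to a directory
#'
#' Emits, per ranking method: the per-family final ranking table
#' (`ranking_<method>.csv`, rank rows x family columns), the post-greedy
#' weights (`weights_<method>.csv`), the greedy selection traces
#' (`trace_<method>.csv`), and — when evaluation ran — the prefix search
#' (`prefix_<method>.csv`), the metrics table (`metrics_<method>.csv`) and ROC
#' points (`roc_<method>.csv`). The two-column ensemble ranking goes to
#' `ranking_ensemble.csv`, and the configuration snapshot to `config.json`.
#'
#' @param run a `retinorank_run`.
#' @param dir output directory (created if needed).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  for (method in run$config$methods) {
    wcsv(run$model_tables[[method]], paste0("ranking_", method, ".csv"))
    wcsv(run$weights[run$weights$method == method, ],
         paste0("weights_", method, ".csv"))
    wcsv(run$traces[run$traces$method == method, ],
         paste0("trace_", method, ".csv"))
    if (!is.null(run$prefix)) {
      pf <- do.call(rbind, lapply(names(run$prefix[[method]]), function(fid) {
        data.frame(model = fid, run$prefix[[method]][[fid]]$prefix_aucs)
      }))
      wcsv(pf, paste0("prefix_", method, ".csv"))
      wcsv(run$metrics[run$metrics$method == method, ],
           paste0("metrics_", method, ".csv"))
      wcsv(run$roc[run$roc$method == method, ], paste0("roc_", method, ".csv"))
    }
  }
  ens <- data.frame(rank = seq_len(nrow(run$ensemble[[1]]$ranking)))
  for (method in run$config$methods) {
    ens[[method]] <- run$ensemble[[method]]$ranking$factor
  }
  wcsv(ens, "ranking_ensemble.csv")
  snap <- run$config
  snap$output_dir <- NULL  # environment detail, not part of the analysis config
  snap$specs <- do.call(rbind, c(lapply(snap$specs, function(sp) {
    data.frame(name = sp$name, kind = sp$kind,
               rate = sp$rate %||% NA, mean = sp$mean %||% NA,
               sd = sp$sd %||% NA, effect = sp$effect,
               lower = as.character(sp$lower))
  }), list(make.row.names = FALSE)))
  jsonlite::write_json(unclass(snap), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(dir)
}

#' @export
print.retinorank_run <- function(x, ...) {
  cat(sprintf("<retinorank_run> %d subjects, methods: %s, %d repeats\n",
              nrow(x$cohort$data), paste(x$config$methods, collapse = "+"),
              x$config$repeats))
  for (m in names(x$ensemble)) {
    cat(sprintf("  %s ensemble ranking: %s\n", m,
                paste(x$ensemble[[m]]$ranking$factor, collapse = " > ")))
  }
  if (!is.null(x$metrics)) {
    print(x$metrics[, c("method", "model", "sensitivity", "specificity",
                        "auc", "accuracy")], row.names = FALSE)
  }
  invisible(x)
}
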