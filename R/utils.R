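#' Derive a stage-specific random seed from a base seed
#'
#' Every stochastic stage of the pipeline consumes its own seed derived
#' deterministically from the single run seed, so any stage can be re-run in
#' isolation and two runs with the same configuration are bit-identical.
#' The derivation hashes the stage label and an optional index into a 31-bit
#' integer.
#'
#' @param seed base integer seed.
#' @param label character stage label (e.g. "split", "smote").
#' @param index optional non-negative integer (e.g. repeat number).
#' @return an integer seed in [0, 2^31 - 1].
#' @export
derive_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  val <- (as.numeric(seed) %% 2147483647) * 69069 + h * 7919 + index * 104729
  as.integer(val %% 2147483647)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified row subsample
#'
#' Returns sorted row indices of a stratified subsample: at most `cap` rows,
#' class proportions preserved, at least one row per class. Used to bound
#' model-fitting cost in the ranking and selection stages.
#'
#' @param labels class label vector.
#' @param cap maximum number of rows.
#' @param seed integer seed.
#' @return sorted integer vector of row indices.
#' @export
stratified_cap <- function(labels, cap, seed) {
  n <- length(labels)
  if (n <= cap) return(seq_len(n))
  local_seed(seed, {
    idx <- unlist(lapply(split(seq_len(n), labels), function(ix) {
      m <- max(1L, round(length(ix) / n * cap))
      sample(ix, min(m, length(ix)))
    }), use.names = FALSE)
    sort(idx)
  })
}
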