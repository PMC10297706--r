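# Shared fixtures, built in code.

# A small, fully numeric two-class dataset with one informative feature and
# optional noise features.
make_classification <- function(n = 200, n_noise = 2, beta = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (1 + n_noise)), n,
                dimnames = list(NULL, c("signal", paste0("noise", seq_len(n_noise)))))
    y <- rbinom(n, 1, plogis(beta * x[, "signal"]))
    list(x = x, y = y)
  })
}

# Hand-built cohort from a data.frame plus factor kinds.
make_cohort <- function(data, labels, kinds) {
  specs <- lapply(names(data), function(nm) {
    if (kinds[[nm]] == "binary") {
      factor_spec(nm, "binary", rate = 0.5)
    } else {
      factor_spec(nm, "continuous", mean = 0, sd = 1)
    }
  })
  names(specs) <- names(data)
  structure(list(data = data, labels = as.integer(labels), specs = specs,
                 seed = NA_integer_), class = "cohort")
}

# Zeroed-effect spec set (labels independent of every factor).
null_specs <- function() {
  specs <- default_dr_specs()
  for (nm in names(specs)) specs[[nm]]$effect <- 0
  specs
}

# Random bounded value function over subsets of d features, fixed by seed:
# v(S, x) depends only on S (instance-constant game), handy for axiom tests.
random_game <- function(d, seed) {
  vals <- withr::with_seed(seed, stats::setNames(
    runif(2^d), vapply(0:(2^d - 1), function(m) mask_key(m, d), "")))
  function(cols, x) rep(vals[[mask_key(sum(bitwShiftL(1L, cols - 1L)), d)]],
                        nrow(x))
}

mask_key <- function(mask, d) paste0("m", mask)

# Brute-force Shapley values of an instance-constant game by enumerating all
# d! feature orderings and averaging marginal contributions.
shapley_bruteforce <- function(d, f, x) {
  perms <- all_permutations(seq_len(d))
  phi <- numeric(d)
  for (perm in perms) {
    prev <- f(integer(0), x)[1]
    cols <- integer(0)
    for (i in perm) {
      cols <- c(cols, i)
      cur <- f(cols, x)[1]
      phi[i] <- phi[i] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(perms)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (tail in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], tail)
  }
  out
}
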