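# Internal helpers shared across modules.

#' Derive a module-specific seed from a master seed
#'
#' One master seed per run; per-module seeds are derived by stable hashing so
#' modules do not consume each other's random streams.
#'
#' @param master integer master seed.
#' @param module character tag.
#' @return an integer seed in \[0, 2^31).
#' @export
derive_seed <- function(master, module) {
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)))
  as.integer((abs(as.numeric(master)) * 69069 + h * 1013 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified fold assignment
#'
#' Assigns each instance to one of `k` folds so that every class is spread as
#' evenly as possible across folds.
#'
#' @param y factor of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(y, k, seed = 0L) {
  y <- as.factor(y)
  if (min(table(y)) < k) {
    stop("smallest class has fewer instances (", min(table(y)),
         ") than folds (", k, ")")
  }
  folds <- integer(length(y))
  rng <- local_rng(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[rng$sample_idx(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Small RNG wrapper: isolates seeded draws from the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    res <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    res
  }
  list(
    runif = function(n, ...) with_state(function() runif(n, ...)),
    rnorm = function(n, ...) with_state(function() rnorm(n, ...)),
    sample_idx = function(n, size = n, replace = FALSE)
      with_state(function() sample.int(n, size = size, replace = replace)),
    with = with_state
  )
}

# Evaluate `expr` with the global RNG temporarily seeded; restores state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  force(expr)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(name, " must be a positive finite scalar")
}
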