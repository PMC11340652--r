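# Shapley-value attribution of classifier decisions to descriptors and, via
# the meta-classifier, to organs.
#
# The value function is interventional: v(S) is the mean model output when
# the features in coalition S take the explained instance's values and the
# remaining features are drawn from background rows. shapley_exact enumerates
# all 2^m coalitions; shapley_sampled is the Monte-Carlo permutation
# estimator (mean marginal contribution over random feature orderings).

MAX_EXACT_FEATURES <- 14L

#' Exact Shapley values of a black-box scorer
#'
#' Enumerates all coalitions, imputing absent features from background rows
#' (interventional expectation), and applies the classical Shapley weights.
#' Satisfies local accuracy and symmetry exactly.
#'
#' @param f scorer: `function(X)` mapping a numeric matrix (rows = instances)
#'   to a numeric vector of outputs.
#' @param instance named numeric vector, the instance to explain (m <= 14).
#' @param background numeric matrix of background rows (same columns).
#' @return numeric vector of per-feature Shapley values with attribute
#'   `baseline` (mean output over the background).
#' @export
shapley_exact <- function(f, instance, background) {
  m <- length(instance)
  if (m > MAX_EXACT_FEATURES)
    stop("exact enumeration limited to ", MAX_EXACT_FEATURES,
         " features; use shapley_sampled()")
  background <- as.matrix(background)
  stopifnot(ncol(background) == m)
  nb <- nrow(background)
  n_coal <- bitwShiftL(1L, m)
  # v(S) for every coalition, batched into one scorer call per chunk
  v <- numeric(n_coal)
  chunk <- max(1L, floor(20000 / nb))
  for (start in seq(0L, n_coal - 1L, by = chunk)) {
    ss <- start:min(start + chunk - 1L, n_coal - 1L)
    rows <- matrix(NA_real_, length(ss) * nb, m)
    for (j in seq_along(ss)) {
      X <- background
      on_bits <- which(bitwAnd(ss[j], bitwShiftL(1L, 0:(m - 1))) != 0L)
      if (length(on_bits)) X[, on_bits] <- rep(instance[on_bits], each = nb)
      rows[((j - 1) * nb + 1):(j * nb), ] <- X
    }
    colnames(rows) <- names(instance)
    out <- f(rows)
    v[ss + 1L] <- colMeans(matrix(out, nb, length(ss)))
  }
  fact <- factorial(0:m)
  w <- fact[1:m] * fact[m:1] / fact[m + 1]   # w[s+1] = s! (m-1-s)! / m!
  sizes <- vapply(0:(n_coal - 1L), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(m - 1))) != 0L), numeric(1))
  phi <- numeric(m)
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    no_i <- which(bitwAnd(0:(n_coal - 1L), bit) == 0L)  # 1-based: S = no_i - 1
    phi[i] <- sum(w[sizes[no_i] + 1L] * (v[no_i + bit] - v[no_i]))
  }
  names(phi) <- names(instance)
  attr(phi, "baseline") <- v[1L]
  phi
}

#' Monte-Carlo permutation estimator of Shapley values
#'
#' Averages marginal contributions over seeded random feature orderings;
#' reports the Monte-Carlo standard error per feature.
#'
#' @inheritParams shapley_exact
#' @param n_permutations number of random orderings (>= 100).
#' @param seed integer seed.
#' @return numeric vector of Shapley values with attributes `se` (standard
#'   errors) and `baseline`.
#' @export
shapley_sampled <- function(f, instance, background, n_permutations = 1000L,
                            seed = 0L) {
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  m <- length(instance)
  background <- as.matrix(background)
  nb <- nrow(background)
  rng <- local_rng(derive_seed(seed, "shapley"))
  baseline <- mean(f(background))
  contrib <- matrix(0, n_permutations, m)
  chunk <- max(1L, floor(20000 / (nb * m)))
  p <- 1L
  while (p <= n_permutations) {
    ps <- p:min(p + chunk - 1L, n_permutations)
    orders <- lapply(ps, function(.) rng$sample_idx(m))
    # rows: for each permutation, m cumulative replacement stages
    rows <- matrix(NA_real_, length(ps) * m * nb, m)
    off <- 0L
    for (ord in orders) {
      X <- background
      for (j in ord) {
        X[, j] <- instance[j]
        rows[(off + 1):(off + nb), ] <- X
        off <- off + nb
      }
    }
    colnames(rows) <- names(instance)
    vals <- colMeans(matrix(f(rows), nb))   # one v per stage
    off <- 0L
    for (k in seq_along(orders)) {
      vstage <- vals[(off / nb + 1):(off / nb + m)]
      contrib[ps[k], orders[[k]]] <- diff(c(baseline, vstage))
      off <- off + m * nb
    }
    p <- p + chunk
  }
  phi <- colMeans(contrib)
  names(phi) <- names(instance)
  attr(phi, "se") <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  attr(phi, "baseline") <- baseline
  phi
}

# per-class scorer for a fitted olive_base / backend on raw descriptor scale
base_class_scorer <- function(model, class) {
  function(X) {
    P <- predict_prob_classes(model$backend,
                              apply_scaler(model$scaler, as.matrix(X)),
                              model$classes)
    P[, class]
  }
}

#' Per-feature Shapley importance report for an organ classifier
#'
#' Computes per-instance, per-class Shapley values of the predicted class
#' probabilities, and ranks features by the spread (mean absolute value) of
#' their Shapley values across instances and classes — a wider spread means
#' the feature moves the model output more and is therefore more important.
#'
#' @param model a fitted [train_base()] classifier.
#' @param table the `olive_features` table to explain.
#' @param mode `"exact"` (m <= 14 features) or `"sampled"`.
#' @param n_instances explain at most this many instances (seeded subsample).
#' @param background_size background rows for the value function (<= 100).
#' @param n_permutations permutations for sampled mode.
#' @param seed integer seed.
#' @return object of class `shapley_summary`: `values` (long data frame:
#'   instance, class, feature, value), `spread` (named mean |value| per
#'   feature), `ranking` (features, most important first), `baseline`.
#' @export
feature_importance_report <- function(model, table, mode = c("sampled", "exact"),
                                      n_instances = 50L, background_size = 100L,
                                      n_permutations = 500L, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "olive_base"))
  if (!identical(model$feature_names, attr(table, "feature_names")))
    stop("feature names of model and table differ")
  X <- feature_matrix(table)
  if (mode == "exact" && ncol(X) > MAX_EXACT_FEATURES)
    stop("exact mode limited to ", MAX_EXACT_FEATURES, " features")
  rng <- local_rng(derive_seed(seed, "importance"))
  bg <- X[rng$sample_idx(nrow(X), min(background_size, nrow(X))), , drop = FALSE]
  inst_idx <- sort(rng$sample_idx(nrow(X), min(n_instances, nrow(X))))
  out <- list()
  for (cl in model$classes) {
    f <- base_class_scorer(model, cl)
    for (i in inst_idx) {
      phi <- if (mode == "exact") shapley_exact(f, X[i, ], bg)
             else shapley_sampled(f, X[i, ], bg, n_permutations,
                                  seed = derive_seed(seed, paste0(cl, i)))
      out[[length(out) + 1L]] <- data.frame(
        instance = table$sample_id[i], class = cl,
        feature = names(phi), value = as.numeric(phi))
    }
  }
  long <- do.call(rbind, out)
  spread <- tapply(abs(long$value), long$feature, mean)
  spread <- spread[order(-spread)]
  structure(list(values = long, spread = spread,
                 ranking = names(spread), mode = mode),
            class = "shapley_summary")
}

#' @export
print.shapley_summary <- function(x, ...) {
  cat("<shapley_summary>", length(x$ranking), "features,",
      length(unique(x$values$instance)), "instances\n")
  cat("top features (mean |Shapley|):\n")
  print(utils::head(round(x$spread, 5), 8))
  invisible(x)
}

#' Per-cultivar organ contributions from the stacking meta-classifier
#'
#' Shapley values are computed on the meta-classifier's probability inputs
#' (3 x n_classes columns). For each cultivar, the weight of an organ is the
#' mean absolute Shapley value summed over that organ's probability columns
#' for instances of the cultivar, normalized so the three organ weights sum
#' to 1.
#'
#' @param model a fitted [olive_stack()].
#' @param joint the [pair_organs()] instances to attribute.
#' @param n_instances per-cultivar cap on explained instances.
#' @param background_size background rows for the value function.
#' @param n_permutations permutations when the meta input is too wide for
#'   exact enumeration.
#' @param seed integer seed.
#' @return data frame with columns `cultivar`, `fruit`, `leaf`, `endocarp`
#'   (rows sum to 1).
#' @export
organ_contribution <- function(model, joint, n_instances = 20L,
                               background_size = 50L, n_permutations = 300L,
                               seed = 0L) {
  stopifnot(inherits(model, "olive_stack"))
  Pin <- predict(model, joint, type = "meta_input")
  y <- joint$instances$cultivar
  rng <- local_rng(derive_seed(seed, "organ"))
  bg <- Pin[rng$sample_idx(nrow(Pin), min(background_size, nrow(Pin))), , drop = FALSE]
  exact_ok <- ncol(Pin) <= MAX_EXACT_FEATURES
  out <- list()
  for (cl in model$classes) {
    f <- function(X) predict_prob_classes(model$meta, as.matrix(X),
                                          model$classes)[, cl]
    idx <- which(y == cl)
    if (length(idx) > n_instances) idx <- idx[rng$sample_idx(length(idx), n_instances)]
    absval <- matrix(0, length(idx), ncol(Pin))
    for (k in seq_along(idx)) {
      phi <- if (exact_ok) shapley_exact(f, Pin[idx[k], ], bg)
             else shapley_sampled(f, Pin[idx[k], ], bg, n_permutations,
                                  seed = derive_seed(seed, paste0("oc", cl, k)))
      absval[k, ] <- abs(phi)
    }
    mean_abs <- colMeans(absval)
    w <- vapply(model$organ_cols, function(cols) sum(mean_abs[cols]), numeric(1))
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / 3, 3)
    out[[cl]] <- data.frame(cultivar = cl, fruit = w[["fruit"]],
                            leaf = w[["leaf"]], endocarp = w[["endocarp"]])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
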