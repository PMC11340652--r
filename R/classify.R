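# Per-organ probabilistic base classifiers and the stacking meta-classifier.
#
# The stacking procedure: (1) a stratified 1/10 of the joint instances is held
# out; (2) the remaining 9/10 is split into 5 stratified folds, and for each
# fold the three organ classifiers are trained on the other 4/5 and predict
# the held fold, yielding out-of-fold probability matrices; (3) the
# meta-classifier is trained on the concatenated probability vectors
# (3 x n_classes inputs); (4) cross-validation on that meta training set
# yields the cv report, and the 1/10 holdout is scored separately with base
# models refit on the full 9/10.

#' Base classifier specification
#'
#' @param algorithm one of `"xgboost"` (gradient-boosted trees, the default),
#'   `"random_forest"`, `"knn"`, `"svm"` (RBF, with probability calibration).
#' @param params named list of hyperparameter overrides passed to the backend.
#' @return a `base_spec` object.
#' @export
base_spec <- function(algorithm = c("xgboost", "random_forest", "knn", "svm"),
                      params = list()) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, params = params), class = "base_spec")
}

# Default hyperparameters per backend (echoed into fitted objects).
default_params <- function(algorithm) {
  switch(algorithm,
    xgboost = list(nrounds = 60, max_depth = 3, eta = 0.3, nthread = 1,
                   tree_method = "exact", subsample = 1, verbosity = 0),
    random_forest = list(ntree = 300),
    knn = list(k = 5),
    svm = list(kernel = "radial", cost = 1))
}

# Fit one probabilistic classifier on a standardized matrix. Returns an object
# with a predict_prob(X) method returning a row-stochastic matrix whose
# columns follow `classes`.
fit_backend <- function(X, y, spec, seed) {
  classes <- levels(y)
  prm <- modifyList(default_params(spec$algorithm), spec$params)
  model <- switch(spec$algorithm,
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      with_seed(seed, xgboost::xgb.train(
        params = c(list(objective = "multi:softprob",
                        num_class = length(classes),
                        eval_metric = "mlogloss"),
                   prm[setdiff(names(prm), "nrounds")]),
        data = dtrain, nrounds = prm$nrounds))
    },
    random_forest = with_seed(seed, randomForest::randomForest(
      x = X, y = y, ntree = prm$ntree)),
    knn = caret::knn3(x = X, y = y, k = prm$k),
    svm = with_seed(seed, e1071::svm(
      x = X, y = y, probability = TRUE, kernel = prm$kernel, cost = prm$cost)))
  structure(list(model = model, algorithm = spec$algorithm, classes = classes,
                 params = prm), class = "olive_backend")
}

predict_prob <- function(object, X) {
  classes <- object$classes
  P <- switch(object$algorithm,
    xgboost = {
      p <- predict(object$model, xgboost::xgb.DMatrix(X))
      if (is.null(dim(p)))   # older interface returns a row-major vector
        p <- matrix(p, ncol = length(classes), byrow = TRUE)
      dimnames(p) <- list(NULL, classes)
      p
    },
    random_forest = predict(object$model, X, type = "prob"),
    knn = predict(object$model, X, type = "prob"),
    svm = {
      pr <- predict(object$model, X, probability = TRUE)
      attr(pr, "probabilities")
    })
  P <- P[, classes, drop = FALSE]
  P / pmax(rowSums(P), 1e-12)
}

# z-score scaler fit on training rows only.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(scaler, X) sweep(sweep(X, 2, scaler$mu), 2, scaler$sd, "/")

#' Train a per-organ base classifier with cross-validated accuracy
#'
#' Features are z-scored with statistics fit on the training folds only;
#' accuracy is estimated by stratified k-fold cross-validation and the final
#' model is refit on all rows.
#'
#' @param table an `olive_features` table with >= 2 cultivars and >= 5
#'   instances in the smallest cultivar.
#' @param spec a [base_spec()].
#' @param cv_folds number of CV folds (default 5).
#' @param seed integer seed.
#' @return an object of class `olive_base` with elements `backend`, `scaler`,
#'   `cv_accuracy` (mean), `cv_sd`, `fold_accuracy`, `classes`,
#'   `feature_names`.
#' @export
train_base <- function(table, spec = base_spec(), cv_folds = 5L, seed = 0L) {
  X <- feature_matrix(table)
  y <- factor(table$cultivar)
  if (nlevels(y) < 2) stop("need at least 2 cultivars")
  if (min(table(y)) < 5) stop("need >= 5 instances per cultivar")
  folds <- stratified_folds(y, cv_folds, derive_seed(seed, "folds"))
  acc <- numeric(cv_folds)
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    sc <- fit_scaler(X[tr, , drop = FALSE])
    fit <- fit_backend(apply_scaler(sc, X[tr, , drop = FALSE]),
                       droplevels(y[tr]), spec, derive_seed(seed, paste0("cv", k)))
    P <- predict_prob_classes(fit, apply_scaler(sc, X[!tr, , drop = FALSE]),
                              levels(y))
    acc[k] <- mean(levels(y)[max.col(P, ties.method = "first")] == y[!tr])
  }
  sc <- fit_scaler(X)
  backend <- fit_backend(apply_scaler(sc, X), y, spec, derive_seed(seed, "final"))
  structure(list(backend = backend, scaler = sc,
                 cv_accuracy = mean(acc), cv_sd = stats::sd(acc),
                 fold_accuracy = acc, classes = levels(y),
                 feature_names = attr(table, "feature_names"),
                 organ = attr(table, "organ"), spec = spec),
            class = "olive_base")
}

# probability matrix with a fixed global class order (absent classes get 0).
predict_prob_classes <- function(backend, X, classes) {
  P <- predict_prob(backend, X)
  out <- matrix(0, nrow(X), length(classes), dimnames = list(NULL, classes))
  out[, colnames(P)] <- P
  out / pmax(rowSums(out), 1e-12)
}

#' @export
predict.olive_base <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "olive_features")) feature_matrix(newdata)
       else as.matrix(newdata[, object$feature_names, drop = FALSE])
  P <- predict_prob_classes(object$backend, apply_scaler(object$scaler, X),
                            object$classes)
  if (type == "prob") P else factor(object$classes[max.col(P, ties.method = "first")],
                                    levels = object$classes)
}

#' @export
print.olive_base <- function(x, ...) {
  cat(sprintf("<olive_base> %s on %s features; CV accuracy %.3f +/- %.3f (%d classes)\n",
              x$backend$algorithm, x$organ, x$cv_accuracy, x$cv_sd,
              length(x$classes)))
  invisible(x)
}

#' Pair fruit, leaf and endocarp rows into joint instances
#'
#' Within each cultivar, fruit and endocarp rows are paired by shared
#' `sample_id` (endocarps are extracted from the sampled fruits); leaves are
#' paired by a seeded random permutation. The count per cultivar is the
#' minimum of the three organ counts; cultivars absent from any table are
#' excluded with a warning.
#'
#' @param fruit,leaf,endocarp `olive_features` tables.
#' @param seed integer seed for the leaf permutation.
#' @return an object of class `olive_joint`: the three tables plus an
#'   `instances` data frame with `cultivar` and row indices into each table.
#' @export
pair_organs <- function(fruit, leaf, endocarp, seed = 0L) {
  cvs <- Reduce(intersect, list(unique(fruit$cultivar), unique(leaf$cultivar),
                                unique(endocarp$cultivar)))
  all_cvs <- unique(c(fruit$cultivar, leaf$cultivar, endocarp$cultivar))
  if (length(setdiff(all_cvs, cvs)))
    warning("cultivars missing from some organ table excluded: ",
            paste(setdiff(all_cvs, cvs), collapse = ", "))
  rng <- local_rng(derive_seed(seed, "pairing"))
  inst <- list()
  for (cv in sort(cvs)) {
    fi <- which(fruit$cultivar == cv)
    ei <- which(endocarp$cultivar == cv)
    li <- which(leaf$cultivar == cv)
    shared <- intersect(fruit$sample_id[fi], endocarp$sample_id[ei])
    fi <- fi[match(shared, fruit$sample_id[fi])]
    ei <- ei[match(shared, endocarp$sample_id[ei])]
    n <- min(length(shared), length(li))
    if (n == 0L) next
    li <- li[rng$sample_idx(length(li))][seq_len(n)]
    inst[[cv]] <- data.frame(cultivar = cv, fruit_row = fi[seq_len(n)],
                             leaf_row = li, endocarp_row = ei[seq_len(n)])
  }
  structure(list(fruit = fruit, leaf = leaf, endocarp = endocarp,
                 instances = do.call(rbind, c(inst, list(make.row.names = FALSE)))),
            class = "olive_joint")
}

#' @export
print.olive_joint <- function(x, ...) {
  cat(sprintf("<olive_joint> %d instances, %d cultivars\n",
              nrow(x$instances), length(unique(x$instances$cultivar))))
  invisible(x)
}

joint_matrices <- function(joint) {
  list(fruit = feature_matrix(joint$fruit)[joint$instances$fruit_row, , drop = FALSE],
       leaf = feature_matrix(joint$leaf)[joint$instances$leaf_row, , drop = FALSE],
       endocarp = feature_matrix(joint$endocarp)[joint$instances$endocarp_row, , drop = FALSE])
}

#' Fit the stacking meta-classifier over the three organ classifiers
#'
#' Implements the two-level procedure described above: stratified 1/10
#' holdout, 5-fold out-of-fold probability matrices from the per-organ base
#' classifiers, meta-classifier trained on the concatenated probabilities,
#' cross-validated metrics on the meta training set, and holdout metrics from
#' base models refit on the full 9/10.
#'
#' @param joint an [pair_organs()] object.
#' @param base_specs named list of [base_spec()]s for `fruit`, `leaf`,
#'   `endocarp` (a single spec is recycled).
#' @param meta_spec [base_spec()] for the meta-classifier. The default is a
#'   random forest: bagged trees vote across all probability columns, whereas
#'   greedy boosting tends to read a single organ's block when the meta
#'   training probabilities are separable.
#' @param seed integer seed.
#' @param holdout_frac fraction held out for the final test (default 1/10).
#' @param inner_folds folds used to generate out-of-fold probabilities
#'   (default 5).
#' @param cv_folds folds for the meta-level cross-validated report.
#' @return an object of class `olive_stack`.
#' @export
olive_stack <- function(joint, base_specs = base_spec(),
                        meta_spec = base_spec("random_forest"),
                        seed = 0L, holdout_frac = 0.1, inner_folds = 5L,
                        cv_folds = 5L) {
  stopifnot(inherits(joint, "olive_joint"))
  if (inherits(base_specs, "base_spec"))
    base_specs <- list(fruit = base_specs, leaf = base_specs,
                       endocarp = base_specs)
  y <- factor(joint$instances$cultivar)
  classes <- levels(y)
  Xs <- joint_matrices(joint)
  n <- length(y)

  # (1) stratified holdout
  ho_folds <- stratified_folds(y, round(1 / holdout_frac),
                               derive_seed(seed, "holdout"))
  holdout <- ho_folds == 1L
  ytr <- droplevels(y[!holdout])

  # (2) out-of-fold probability matrices on the 9/10
  folds <- stratified_folds(ytr, inner_folds, derive_seed(seed, "inner"))
  P_oof <- matrix(NA_real_, sum(!holdout), 3 * length(classes))
  organ_cols <- setNames(lapply(seq_along(Xs), function(i)
    (i - 1L) * length(classes) + seq_along(classes)), names(Xs))
  fold_of_row <- folds
  for (k in seq_len(inner_folds)) {
    tr <- folds != k
    for (org in names(Xs)) {
      Xtr <- Xs[[org]][!holdout, , drop = FALSE]
      sc <- fit_scaler(Xtr[tr, , drop = FALSE])
      fit <- fit_backend(apply_scaler(sc, Xtr[tr, , drop = FALSE]),
                         droplevels(ytr[tr]), base_specs[[org]],
                         derive_seed(seed, paste0(org, ":oof", k)))
      P_oof[!tr, organ_cols[[org]]] <-
        predict_prob_classes(fit, apply_scaler(sc, Xtr[!tr, , drop = FALSE]),
                             classes)
    }
  }
  colnames(P_oof) <- unlist(lapply(names(Xs), function(o) paste(o, classes, sep = ".")))

  # (3) meta-classifier on the out-of-fold probabilities
  meta <- fit_backend(P_oof, ytr, meta_spec, derive_seed(seed, "meta"))

  # (4) cross-validated metrics on the meta training set
  meta_folds <- stratified_folds(ytr, cv_folds, derive_seed(seed, "metacv"))
  cv_pred <- factor(rep(NA_character_, length(ytr)), levels = classes)
  for (k in seq_len(cv_folds)) {
    tr <- meta_folds != k
    fit <- fit_backend(P_oof[tr, , drop = FALSE], droplevels(ytr[tr]),
                       meta_spec, derive_seed(seed, paste0("metacv", k)))
    P <- predict_prob_classes(fit, P_oof[!tr, , drop = FALSE], classes)
    cv_pred[!tr] <- classes[max.col(P, ties.method = "first")]
  }
  cv_report <- classification_report(ytr, cv_pred)

  # base models refit on the full 9/10 for deployment / holdout scoring
  base_models <- lapply(names(Xs), function(org) {
    Xtr <- Xs[[org]][!holdout, , drop = FALSE]
    sc <- fit_scaler(Xtr)
    list(backend = fit_backend(apply_scaler(sc, Xtr), ytr, base_specs[[org]],
                               derive_seed(seed, paste0(org, ":full"))),
         scaler = sc)
  })
  names(base_models) <- names(Xs)

  obj <- structure(list(
    base_models = base_models, meta = meta, classes = classes,
    organ_cols = organ_cols, cv_report = cv_report,
    holdout_idx = which(holdout), fold_of_row = fold_of_row,
    seed = seed, base_specs = base_specs, meta_spec = meta_spec),
    class = "olive_stack")

  P_ho_in <- stack_probs(obj, lapply(Xs, function(X) X[holdout, , drop = FALSE]))
  P_ho <- predict_prob_classes(meta, P_ho_in, classes)
  ho_pred <- factor(classes[max.col(P_ho)], levels = classes)
  obj$holdout <- list(truth = factor(y[holdout], levels = classes),
                      pred = ho_pred, prob = P_ho,
                      accuracy = mean(ho_pred == y[holdout]),
                      report = classification_report(y[holdout], ho_pred))
  obj
}

# concatenated base-probability matrix for new per-organ feature matrices
stack_probs <- function(object, Xs) {
  P <- matrix(0, nrow(Xs[[1]]), 3 * length(object$classes))
  for (org in names(object$base_models)) {
    bm <- object$base_models[[org]]
    P[, object$organ_cols[[org]]] <-
      predict_prob_classes(bm$backend, apply_scaler(bm$scaler, Xs[[org]]),
                           object$classes)
  }
  colnames(P) <- unlist(lapply(names(object$base_models),
                               function(o) paste(o, object$classes, sep = ".")))
  P
}

#' @export
predict.olive_stack <- function(object, newdata,
                                type = c("class", "prob", "meta_input"), ...) {
  type <- match.arg(type)
  Xs <- if (inherits(newdata, "olive_joint")) joint_matrices(newdata)
        else newdata
  Pin <- stack_probs(object, Xs)
  if (type == "meta_input") return(Pin)
  P <- predict_prob_classes(object$meta, Pin, object$classes)
  if (type == "prob") P else factor(object$classes[max.col(P, ties.method = "first")],
                                    levels = object$classes)
}

#' @export
print.olive_stack <- function(x, ...) {
  cat(sprintf("<olive_stack> %d cultivars; meta %s over %s base classifiers\n",
              length(x$classes), x$meta$algorithm,
              x$base_models$fruit$backend$algorithm))
  cat(sprintf("  meta-CV accuracy %.3f; holdout accuracy %.3f (n = %d)\n",
              x$cv_report$accuracy, x$holdout$accuracy,
              length(x$holdout$truth)))
  invisible(x)
}

#' @export
summary.olive_stack <- function(object, ...) {
  cat("Stacking meta-classifier\n")
  cat("  classes:", paste(object$classes, collapse = ", "), "\n\n")
  cat("Meta-level cross-validation (out-of-fold probabilities):\n")
  print(object$cv_report$per_class, digits = 3)
  cat(sprintf("  accuracy %.3f\n\n", object$cv_report$accuracy))
  cat("Holdout (1/10):\n")
  print(object$holdout$report$per_class, digits = 3)
  cat(sprintf("  accuracy %.3f\n", object$holdout$accuracy))
  invisible(object)
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest metrics from predicted and true labels. Metrics whose
#' denominator is empty (no predictions, or no instances of a class) are `NA`,
#' not 0.
#'
#' @param truth,pred factors over the same class set.
#' @return list with `per_class` (data frame), `macro` (means over classes)
#'   and `accuracy`.
#' @export
classification_report <- function(truth, pred) {
  classes <- levels(truth)
  pred <- factor(pred, levels = classes)
  tab <- table(truth = truth, pred = pred)
  tp <- diag(tab)
  prec <- ifelse(colSums(tab) > 0, tp / colSums(tab), NA_real_)
  rec <- ifelse(rowSums(tab) > 0, tp / rowSums(tab), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  list(per_class = data.frame(cultivar = classes, precision = as.numeric(prec),
                              recall = as.numeric(rec), f1 = as.numeric(f1)),
       macro = c(precision = mean(prec, na.rm = TRUE),
                 recall = mean(rec, na.rm = TRUE), f1 = mean(f1, na.rm = TRUE)),
       accuracy = mean(pred == truth))
}

#' Repeated-resplit evaluation of the stacking classifier
#'
#' Refits the full stacking procedure over `R` seeded resplits and reports
#' per-class precision/recall/F1 on the holdout as mean +/- sd, the format of
#' a per-cultivar performance table.
#'
#' @param joint an [pair_organs()] object.
#' @param base_specs,meta_spec as in [olive_stack()].
#' @param R number of resplits (default 10).
#' @param seed master seed; resplit r uses seed + r - 1.
#' @return list with `table` (per-class mean and sd of each metric),
#'   `accuracy_mean`, `accuracy_sd` and the per-split reports.
#' @export
evaluate_stacking <- function(joint, base_specs = base_spec(),
                              meta_spec = base_spec("random_forest"),
                              R = 10L, seed = 0L) {
  reports <- vector("list", R)
  accs <- numeric(R)
  for (r in seq_len(R)) {
    fit <- olive_stack(joint, base_specs, meta_spec, seed = seed + r - 1L)
    reports[[r]] <- fit$holdout$report
    accs[r] <- fit$holdout$accuracy
  }
  classes <- reports[[1]]$per_class$cultivar
  agg <- function(metric) {
    M <- vapply(reports, function(rep) rep$per_class[[metric]],
                numeric(length(classes)))
    data.frame(mean = rowMeans(M, na.rm = TRUE),
               sd = apply(M, 1, stats::sd, na.rm = TRUE))
  }
  tab <- data.frame(cultivar = classes,
                    precision = agg("precision"), recall = agg("recall"),
                    f1 = agg("f1"))
  list(table = tab, accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
       reports = reports)
}

#' Classification accuracy as a function of the number of cultivars
#'
#' For each k in `k_range`, draws seeded random subsets of k cultivars, fits
#' the per-organ base classifiers (cross-validated accuracy) and the stacking
#' classifier (meta-CV accuracy) on each subset, and reports means and sds in
#' long format.
#'
#' @param joint an [pair_organs()] object covering all cultivars.
#' @param k_range integer vector of cultivar counts (within \[2, n\]).
#' @param subsets_per_k random subsets per k (default 20; the single
#'   exhaustive subset is used when k equals the number of cultivars).
#' @param seed master seed.
#' @param base_specs,meta_spec classifier specifications.
#' @return data frame with columns `organ` (fruit/leaf/endocarp/stacking),
#'   `k`, `mean`, `sd`.
#' @export
accuracy_vs_k <- function(joint, k_range, subsets_per_k = 20L, seed = 0L,
                          base_specs = base_spec(),
                          meta_spec = base_spec("random_forest")) {
  cvs <- sort(unique(joint$instances$cultivar))
  if (any(k_range < 2 | k_range > length(cvs)))
    stop("k_range outside [2, ", length(cvs), "]")
  if (inherits(base_specs, "base_spec"))
    base_specs <- list(fruit = base_specs, leaf = base_specs,
                       endocarp = base_specs)
  out <- list()
  for (k in k_range) {
    n_sub <- if (k == length(cvs)) 1L else subsets_per_k
    rng <- local_rng(derive_seed(seed, paste0("k", k)))
    accs <- matrix(NA_real_, n_sub, 4,
                   dimnames = list(NULL, c("fruit", "leaf", "endocarp", "stacking")))
    for (s in seq_len(n_sub)) {
      sub_cvs <- cvs[rng$sample_idx(length(cvs), k)]
      sub <- subset_joint(joint, sub_cvs)
      sub_seed <- derive_seed(seed, paste0("k", k, "s", s))
      for (org in c("fruit", "leaf", "endocarp")) {
        tab <- subset_table(joint[[org]], sub_cvs)
        accs[s, org] <- train_base(tab, base_specs[[org]],
                                   seed = sub_seed)$cv_accuracy
      }
      accs[s, "stacking"] <- olive_stack(sub, base_specs, meta_spec,
                                         seed = sub_seed)$cv_report$accuracy
    }
    for (org in colnames(accs)) {
      out[[length(out) + 1L]] <- data.frame(
        organ = org, k = k, mean = mean(accs[, org]),
        sd = if (n_sub > 1) stats::sd(accs[, org]) else NA_real_)
    }
  }
  do.call(rbind, out)
}

subset_table <- function(tab, cultivars) {
  out <- tab[tab$cultivar %in% cultivars, , drop = FALSE]
  structure(out, class = class(tab), feature_names = attr(tab, "feature_names"),
            organ = attr(tab, "organ"))
}

subset_joint <- function(joint, cultivars) {
  keep <- joint$instances$cultivar %in% cultivars
  structure(list(fruit = joint$fruit, leaf = joint$leaf,
                 endocarp = joint$endocarp,
                 instances = joint$instances[keep, , drop = FALSE]),
            class = "olive_joint")
}
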