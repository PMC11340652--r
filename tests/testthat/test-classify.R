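# Base classifiers, organ pairing and the stacking meta-classifier.

test_that("organ pairing follows sample ids, the min rule and the seed", {
  fr <- blob_table("fruit", k = 3, n_per_class = 10, seed = 1)
  en <- blob_table("endocarp", k = 3, n_per_class = 10, seed = 2)
  lf <- blob_table("leaf", k = 3, n_per_class = 10, seed = 3)
  lf$sample_id <- paste0(lf$sample_id, "_L")
  jt <- pair_organs(fr, lf, en, seed = 4)
  expect_identical(nrow(jt$instances), 30L)
  expect_identical(jt$instances$cultivar,
                   jt$fruit$cultivar[jt$instances$fruit_row])
  expect_identical(jt$fruit$sample_id[jt$instances$fruit_row],
                   jt$endocarp$sample_id[jt$instances$endocarp_row])
  jt2 <- pair_organs(fr, lf, en, seed = 4)
  expect_identical(jt$instances, jt2$instances)

  # min rule: drop leaves of one cultivar to 7
  lf7 <- subset(lf, !(cultivar == "cv2" & seq_len(nrow(lf)) %in% which(cultivar == "cv2")[1:3]))
  lf7 <- structure(lf7, class = class(lf), feature_names = attr(lf, "feature_names"),
                   organ = "leaf")
  jt3 <- pair_organs(fr, lf7, en, seed = 4)
  expect_identical(sum(jt3$instances$cultivar == "cv2"), 7L)

  # cultivar present in only some tables is excluded with a warning
  fr4 <- blob_table("fruit", k = 4, n_per_class = 6, seed = 5)
  expect_warning(jt4 <- pair_organs(fr4, lf, en, seed = 0), "excluded")
  expect_setequal(unique(jt4$instances$cultivar), c("cv1", "cv2", "cv3"))
})

test_that("base classifiers separate far-apart cultivars and not noise", {
  tab <- blob_table("fruit", k = 2, n_per_class = 20, sep = 10, seed = 0)
  fit <- train_base(tab, seed = 0)
  expect_gte(fit$cv_accuracy, 0.99)

  null_tab <- tab
  set.seed(1)
  null_tab$cultivar <- sample(null_tab$cultivar)
  fit0 <- train_base(null_tab, seed = 1)
  expect_gte(fit0$cv_accuracy, 0.5 - 0.15)
  expect_lte(fit0$cv_accuracy, 0.5 + 0.15)

  one <- tab[tab$cultivar == "cv1", ]
  one <- structure(one, class = class(tab),
                   feature_names = attr(tab, "feature_names"), organ = "fruit")
  expect_error(train_base(one, seed = 0), "2 cultivars")
})

test_that("all four backends produce row-stochastic probability matrices", {
  tab <- blob_table("fruit", k = 3, n_per_class = 10, sep = 4, seed = 2)
  for (alg in c("xgboost", "random_forest", "knn", "svm")) {
    fit <- train_base(tab, base_spec(alg), seed = 3)
    P <- predict(fit, tab, type = "prob")
    expect_identical(dim(P), c(30L, 3L))
    expect_true(all(abs(rowSums(P) - 1) < 1e-6))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("stacking runs the printed procedure and is seed-deterministic", {
  co <- cached_cohort("separable3", n_per_organ = 10, years = c(1L, 2L), seed = 3)
  jt <- pair_organs(co$fruit, co$leaf, co$endocarp, seed = 1)
  st <- olive_stack(jt, seed = 0)
  expect_identical(ncol(st$holdout$prob), 3L)
  Pin <- predict(st, jt, type = "meta_input")
  expect_identical(ncol(Pin), 9L)      # 3 organs x 3 cultivars
  # each organ block of the meta input is a probability distribution
  for (cols in st$organ_cols)
    expect_true(all(abs(rowSums(Pin[, cols]) - 1) < 1e-6))
  expect_identical(st$holdout$accuracy, 1)

  st2 <- olive_stack(jt, seed = 0)
  expect_identical(st$cv_report, st2$cv_report)
  expect_identical(st$holdout$accuracy, st2$holdout$accuracy)

  # holdout indices never appear in the meta-training fold bookkeeping
  expect_identical(length(st$fold_of_row) + length(st$holdout_idx),
                   nrow(jt$instances))
})

test_that("classification reports match hand-computed confusion metrics", {
  truth <- factor(c(rep("a", 10), rep("b", 10)), levels = c("a", "b"))
  pred <- factor(c(rep("a", 8), rep("b", 2), rep("a", 1), rep("b", 9)),
                 levels = c("a", "b"))
  rep_ <- classification_report(truth, pred)
  expect_equal(rep_$per_class$precision[1], 8 / 9)
  expect_equal(rep_$per_class$recall[1], 0.8)
  expect_equal(rep_$per_class$f1[1], 2 * (8 / 9 * 0.8) / (8 / 9 + 0.8))

  perfect <- classification_report(truth, truth)
  expect_true(all(perfect$per_class$precision == 1))
  expect_true(all(perfect$per_class$f1 == 1))

  all_a <- factor(rep("a", 30), levels = c("a", "b", "c"))
  tr3 <- factor(rep(c("a", "b", "c"), 10), levels = c("a", "b", "c"))
  rep3 <- classification_report(tr3, all_a)
  expect_equal(rep3$per_class$recall[1], 1)
  expect_equal(rep3$per_class$precision[1], 1 / 3)
  expect_true(is.na(rep3$per_class$precision[2]))  # no b predictions: NA, not 0
})

test_that("repeated resplits give a mean +/- sd per-cultivar table", {
  co <- cached_cohort("separable3", n_per_organ = 10, years = c(1L, 2L), seed = 3)
  jt <- pair_organs(co$fruit, co$leaf, co$endocarp, seed = 1)
  ev <- evaluate_stacking(jt, R = 3, seed = 0)
  expect_identical(nrow(ev$table), 3L)
  expect_true(all(c("precision.mean", "precision.sd", "recall.mean", "f1.mean")
                  %in% names(ev$table)))
  expect_gte(ev$accuracy_mean, 0.9)
})

test_that("accuracy_vs_k covers organs and stacking, deterministically", {
  co <- cached_cohort("separable3", n_per_organ = 10, years = c(1L, 2L), seed = 3)
  jt <- pair_organs(co$fruit, co$leaf, co$endocarp, seed = 1)
  curve <- accuracy_vs_k(jt, k_range = c(2, 3), subsets_per_k = 2, seed = 5)
  expect_setequal(unique(curve$organ), c("fruit", "leaf", "endocarp", "stacking"))
  # k = n_cultivars: exactly one subset, sd is NA
  expect_true(all(is.na(curve$sd[curve$k == 3])))
  expect_false(any(is.na(curve$sd[curve$k == 2])))
  curve2 <- accuracy_vs_k(jt, k_range = c(2, 3), subsets_per_k = 2, seed = 5)
  expect_identical(curve, curve2)
  expect_error(accuracy_vs_k(jt, k_range = 1:3), "k_range")
})
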