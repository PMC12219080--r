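test_that("confusion counts match hand counts and a tally oracle", {
  cm <- confusion(c("abnormal", "abnormal", "normal", "normal"),
                  c("abnormal", "normal", "normal", "abnormal"))
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))

  perfect <- confusion(c("abnormal", "normal"), c("abnormal", "normal"))
  expect_equal(perfect$fp + perfect$fn, 0L)

  set.seed(2)
  truth <- sample(c("normal", "abnormal"), 100, replace = TRUE)
  pred <- sample(c("normal", "abnormal"), 100, replace = TRUE)
  cm2 <- confusion(truth, pred)
  tally <- table(truth, pred)
  expect_equal(cm2$tp, unname(tally["abnormal", "abnormal"]))
  expect_equal(cm2$tn, unname(tally["normal", "normal"]))
  expect_equal(cm2$fp, unname(tally["normal", "abnormal"]))
  expect_equal(cm2$fn, unname(tally["abnormal", "normal"]))
  expect_error(confusion(c("abnormal", "odd"), c("normal", "normal")),
               "labels")
})

test_that("metric arithmetic and identities hold", {
  m <- compute_metrics(confusion(
    c(rep("abnormal", 55), rep("normal", 45)),
    c(rep("abnormal", 50), rep("normal", 5), rep("abnormal", 5),
      rep("normal", 40))))
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$sensitivity, 50 / 55)
  expect_equal(m$specificity, 40 / 45)

  none <- structure(list(tp = 0L, tn = 10L, fp = 0L, fn = 0L),
                    class = "confusion_matrix")
  expect_warning(m0 <- compute_metrics(none), "sensitivity")
  expect_equal(m0$sensitivity, 0)

  set.seed(6)
  for (rep in 1:20) {
    cm <- structure(as.list(stats::setNames(sample(1:30, 4, TRUE),
                                            c("tp", "tn", "fp", "fn"))),
                    class = "confusion_matrix")
    m <- compute_metrics(cm)
    P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("stratified folds partition indices with near-proportional classes", {
  labels <- rep(c("normal", "abnormal"), each = 50)
  folds <- stratified_kfold(labels, 5, seed = 1)
  expect_equal(sort(unique(folds)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(folds == f & labels == "normal"), 10L)
    expect_equal(sum(folds == f & labels == "abnormal"), 10L)
  }

  lab2 <- c(rep("normal", 47), rep("abnormal", 33))
  f2 <- stratified_kfold(lab2, 5, seed = 2)
  expect_equal(length(f2), 80L)
  for (f in 1:5) {
    expect_lte(abs(sum(f2 == f & lab2 == "normal") - 47 / 5), 1)
    expect_lte(abs(sum(f2 == f & lab2 == "abnormal") - 33 / 5), 1)
  }
  expect_error(stratified_kfold(c("normal", rep("abnormal", 9)), 5), "fewer")
})

test_that("fold assignment and scaling are seed-deterministic", {
  labels <- rep(c("normal", "abnormal"), 25)
  expect_identical(stratified_kfold(labels, 5, 9),
                   stratified_kfold(labels, 5, 9))
  x <- matrix(rnorm(100), 20, 5)
  sc <- fit_feature_scaler(x)
  z <- apply_feature_scaler(sc, x)
  expect_equal(colMeans(z), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  x2 <- x; x2[, 3] <- 7
  z2 <- apply_feature_scaler(fit_feature_scaler(x2), x2)
  expect_true(all(z2[, 3] == 0))  # zero-SD column passes through centred
})

test_that("group comparison detects shifts and matches exhaustive enumeration", {
  set.seed(8)
  labels <- rep(c("normal", "abnormal"), each = 20)
  x <- matrix(rnorm(40), 40, 1)
  x[labels == "abnormal", 1] <- x[labels == "abnormal", 1] + 5
  colnames(x) <- "shifted"
  res <- compare_feature_groups(x, labels, method = "welch")
  expect_lt(res$p_value, 1e-3)
  expect_gt(res$mean_abnormal - res$mean_normal, 4)

  # 4-vs-4 toy split: permutation p against exhaustive enumeration of the
  # 70 equal-size label assignments
  v <- c(0.3, 1.2, 0.8, 0.5, 2.9, 3.4, 2.1, 3.0)
  lab <- rep(c("normal", "abnormal"), each = 4)
  obs <- abs(mean(v[5:8]) - mean(v[1:4]))
  combos <- utils::combn(8, 4)
  exact <- mean(apply(combos, 2, function(idx) {
    abs(mean(v[idx]) - mean(v[-idx])) >= obs - 1e-15
  }))
  mc <- compare_feature_groups(matrix(v, 8, 1), lab, method = "permutation",
                               n_perm = 4000, seed = 3)
  expect_lt(abs(mc$p_value - exact), 0.05)
})

test_that("permutation p-values are calibrated under a true null", {
  set.seed(14)
  labels <- rep(c("normal", "abnormal"), each = 50)
  x <- matrix(rnorm(100 * 200), 100, 200)
  res <- compare_feature_groups(x, labels, method = "permutation",
                                n_perm = 300, seed = 4)
  rate <- mean(res$p_value < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("cross-validation is deterministic and leak-free by construction", {
  gen <- generate_dataset(phantom_params(), n_per_class = 5, seed = 9)
  ft <- feature_table(gen$dataset, test_pipeline_cfg())
  cfg <- test_pipeline_cfg(2L)
  cv1 <- crossvalidate(gen$dataset, cfg, k = 2, seed = 1, features = ft)
  cv2 <- crossvalidate(gen$dataset, cfg, k = 2, seed = 1, features = ft)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(sort(cv1$predictions$id), sort(gen$dataset$ids))
  expect_equal(nrow(cv1$summary), 5L)
})
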