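test_that("mlp topology follows the hidden-layer sizing rule", {
  ds <- tiny_ds(n = 60, d = 14, seed = 1)
  m <- train_classifier(classifier_spec("mlp", epochs = 5), c(0.3, 0.2), ds, seed = 1)
  expect_equal(nrow(m$fit$W1), 8L)           # round((14 + 2) / 2)
  ds3 <- tiny_ds(n = 40, d = 3, seed = 1)
  m3 <- train_classifier(classifier_spec("mlp", epochs = 5), c(0.3, 0.2), ds3, seed = 1)
  expect_equal(nrow(m3$fit$W1), 2L)          # round((3 + 2) / 2) = 2 (banker's)
})

test_that("training is deterministic per seed and validates bounds", {
  ds <- tiny_ds(n = 50, d = 4, sep = 1, seed = 2)
  for (spec in list(classifier_spec("svm"), classifier_spec("mlp", epochs = 30))) {
    p <- evohis:::default_params(spec)
    m1 <- train_classifier(spec, p, ds, seed = 7)
    m2 <- train_classifier(spec, p, ds, seed = 7)
    expect_identical(predict(m1, ds), predict(m2, ds))
  }
  expect_error(train_classifier(classifier_spec("svm"), c(cost = 1.2), ds),
               class = "evohis_bound_violation")
  expect_error(train_classifier(classifier_spec("mlp"), c(0.5), ds),
               class = "evohis_bound_violation")
  one_class <- evohis:::ds_subset(ds, ds$labels == "pos")
  expect_error(train_classifier(classifier_spec("svm"), c(cost = 1), one_class),
               class = "evohis_degenerate_fold")
})

test_that("cost 0 is lifted to an admissible positive cost; rbf kernel works", {
  ds <- tiny_ds(n = 60, d = 3, seed = 4)
  m <- train_classifier(classifier_spec("svm"), c(cost = 0), ds, seed = 1)
  expect_s3_class(m, "evohis_model")
  expect_true(all(!is.na(predict(m, ds))))
  mr <- train_classifier(classifier_spec("svm", kernel = "rbf", gamma = 2),
                         c(cost = 1), ds, seed = 1)
  expect_gt(mean(predict(mr, ds) == ds$labels), 0.9)
})

test_that("mlp is sensitive to learning rate and momentum", {
  ds <- tiny_ds(n = 60, d = 4, sep = 1.5, seed = 6)
  spec <- classifier_spec("mlp", epochs = 40)
  slow <- train_classifier(spec, c(0.001, 0), ds, seed = 3)
  fast <- train_classifier(spec, c(0.9, 0.5), ds, seed = 3)
  expect_false(identical(slow$fit$W1, fast$fit$W1))
  # near-zero learning rate barely moves from random init; fast learns more
  acc <- function(m) mean(predict(m, ds) == ds$labels)
  expect_gt(acc(fast), acc(slow) - 0.05)
})

test_that("stratified folds: balance, replay, and pooled counts partition n", {
  ds <- tiny_ds(n = 103, d = 3, seed = 8, positive_fraction = 0.3)
  fold <- stratified_folds(ds$labels, 10, seed = 5)
  expect_identical(fold, stratified_folds(ds$labels, 10, seed = 5))
  expect_false(identical(fold, stratified_folds(ds$labels, 10, seed = 6)))
  global_frac <- mean(ds$labels == "pos")
  for (k in 1:10) {
    idx <- fold == k
    expect_lte(abs(sum(ds$labels[idx] == "pos") - global_frac * sum(idx)), 1)
  }
  cc <- evaluate_params(classifier_spec("svm"), c(cost = 0.5), ds,
                        cv_config(shuffle_seed = 5), seed = 1)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 103L)
  expect_equal(cc$TP + cc$FN, sum(ds$labels == "pos"))
  expect_equal(cc$TN + cc$FP, sum(ds$labels != "pos"))
})

test_that("evaluate_params replays exactly for a fixed seed and guards fold counts", {
  ds <- tiny_ds(n = 80, d = 4, sep = 2, seed = 9)
  a <- evaluate_params(classifier_spec("svm"), c(cost = 0.7), ds,
                       cv_config(shuffle_seed = 3), seed = 2)
  b <- evaluate_params(classifier_spec("svm"), c(cost = 0.7), ds,
                       cv_config(shuffle_seed = 3), seed = 2)
  expect_identical(a, b)
  skewed <- evohis_dataset(matrix(rnorm(60), 30, 2),
                           rep(c("pos", "neg"), c(4, 26)), positive = "pos")
  expect_error(evaluate_params(classifier_spec("svm"), c(cost = 1), skewed,
                               cv_config(n_folds = 10)),
               class = "evohis_degenerate_fold")
})

test_that("one-hot encoding expands nominal features consistently", {
  X <- cbind(num = c(0.1, 0.5, 0.9, 0.2), cat = c(1, 2, 3, 1))
  ds <- evohis_dataset(X, c("p", "p", "n", "n"), "p",
                       feature_kinds = c("numeric", "nominal"),
                       nominal_levels = list(cat = c("a", "b", "c")))
  enc <- evohis:::encode_features(ds)
  expect_equal(ncol(enc), 4L)   # 1 numeric + 3 indicator columns
  expect_equal(unname(enc[2, ]), c(0.5, 0, 1, 0))
})
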