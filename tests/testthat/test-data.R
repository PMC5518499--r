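test_that("load_dataset reads CSV, flags missing cells and maps the positive class", {
  path <- write_csv_fixture(c("a,b,class", "1,x,yes", "2,,no", "3,x,yes", ",y,no"))
  ds <- load_dataset(path, "csv", label_column = "class", positive_label = "yes")
  expect_s3_class(ds, "evohis_dataset")
  expect_equal(dim(ds), c(4L, 2L))
  expect_equal(sum(ds$missing_mask), 2L)
  expect_equal(levels(ds$labels)[1], "yes")
  expect_equal(ds$feature_kinds, c("numeric", "nominal"))

  expect_error(load_dataset(tempfile(), "csv", "class", "yes"),
               class = "evohis_missing_file")
  expect_error(load_dataset(path, "csv", "nope", "yes"),
               class = "evohis_missing_label_column")
  p3 <- write_csv_fixture(c("a,class", "1,x", "2,y", "3,z"))
  expect_error(load_dataset(p3, "csv", "class", "x"),
               class = "evohis_not_binary")
})

test_that("load_dataset reads ARFF with declared nominals and '?' missing", {
  path <- write_arff_fixture(c(
    "@relation toy", "@attribute a numeric", "@attribute b {low, high}",
    "@attribute class {yes, no}", "@data",
    "1.5, low, yes", "2.0, ?, no", "?, high, yes", "0.5, low, no"))
  ds <- load_dataset(path, "arff", label_column = "class", positive_label = "yes")
  expect_equal(ds$feature_kinds, c("numeric", "nominal"))
  expect_equal(ds$nominal_levels$b, c("low", "high"))
  expect_equal(sum(ds$missing_mask), 2L)
  expect_equal(unname(ds$features[1, "b"]), 1)  # "low" -> declared code 1
})

test_that("impute_missing fills mode (nominal) / mean (numeric), observed cells untouched", {
  X <- cbind(a = c(0, 2, NA, 4), b = c(1, 1, 2, NA))
  ds <- evohis_dataset(X, c("p", "p", "n", "n"), positive = "p",
                       feature_kinds = c("numeric", "nominal"),
                       nominal_levels = list(b = c("A", "B")))
  out <- impute_missing(ds)
  expect_false(any(out$missing_mask))
  expect_equal(unname(out$features[3, "a"]), 2)    # mean(0, 2, 4)
  expect_equal(unname(out$features[4, "b"]), 1)    # mode = A
  expect_equal(out$features[c(1, 2, 4), "a"], X[c(1, 2, 4), "a"])

  # fully-missing feature is unimputable; no-missing dataset is a fixed point
  ds_bad <- evohis_dataset(cbind(a = c(NA, NA, NA), b = 1:3), c("p", "p", "n"), "p")
  expect_error(impute_missing(ds_bad), class = "evohis_unimputable_feature")
  ds_ok <- evohis_dataset(cbind(a = 1:4), c("p", "p", "n", "n"), "p")
  expect_identical(impute_missing(ds_ok), ds_ok)
})

test_that("minmax_normalize maps numeric features to [0,1], constants to 0, idempotent", {
  ds <- evohis_dataset(cbind(a = c(2, 4, 6), b = c(0, 1, 0), k = c(5, 5, 5)),
                       c("p", "p", "n"), "p")
  out <- minmax_normalize(ds)
  expect_equal(unname(out$features[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out$features[, "b"]), c(0, 1, 0))  # already spanning: fixed point
  expect_equal(unname(out$features[, "k"]), c(0, 0, 0))
  expect_identical(minmax_normalize(out), out)
  expect_identical(out$labels, ds$labels)

  ds_na <- evohis_dataset(cbind(a = c(1, NA, 3)), c("p", "n", "n"), "p")
  expect_error(minmax_normalize(ds_na), class = "evohis_has_missing")
})

test_that("preprocessing preserves shape, labels and feature names", {
  ds <- make_synthetic(synthetic_spec(50, 4, missing_rate = 0.1, seed = 3))
  out <- minmax_normalize(impute_missing(ds))
  expect_equal(dim(out), dim(ds))
  expect_identical(out$labels, ds$labels)
  expect_identical(out$feature_names, ds$feature_names)
  expect_true(all(out$features >= 0 & out$features <= 1))
})

test_that("supervised_resample: size, determinism, bias-to-uniform expectation", {
  ds <- tiny_ds(n = 200, seed = 5)
  out <- supervised_resample(ds, seed = 1)
  expect_equal(nrow(out$features), 200L)
  expect_identical(supervised_resample(ds, seed = 9),
                   supervised_resample(ds, seed = 9))
  half <- supervised_resample(ds, seed = 1, size_percent = 50)
  expect_equal(nrow(half$features), 100L)
  expect_error(supervised_resample(ds, 1, size_percent = 0.1),
               class = "evohis_empty_resample")

  # 900/100 imbalance, bias 1: positive draws ~ Binomial(1000, 0.5)
  y <- rep(c("pos", "neg"), c(900, 100))
  big <- evohis_dataset(matrix(rnorm(2000), 1000, 2), y, positive = "pos")
  hits <- vapply(1:20, function(s) {
    r <- supervised_resample(big, seed = s, bias_to_uniform = 1)
    abs(sum(r$labels == "pos") - 500) <= 47
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("supervised_resample with bias 0 preserves class proportions (chi-square)", {
  ds <- tiny_ds(n = 150, seed = 21)
  m1 <- sum(ds$labels == "pos")
  pos <- sum(vapply(1:50, function(s)
    sum(supervised_resample(ds, seed = s)$labels == "pos"), 0))
  total <- 50L * nrow(ds$features)
  p <- stats::chisq.test(c(pos, total - pos),
                         p = c(m1, nrow(ds$features) - m1) / nrow(ds$features))$p.value
  expect_gt(p, 0.001)
})

test_that("make_synthetic: reproducibility, class balance, separation behavior", {
  spec <- synthetic_spec(100, 5, class_separation = 6, seed = 7)
  expect_identical(make_synthetic(spec), make_synthetic(spec))
  spec2 <- spec; spec2$seed <- 8L
  expect_false(identical(make_synthetic(spec), make_synthetic(spec2)))

  npos <- sum(make_synthetic(synthetic_spec(100, 3, seed = 1))$labels == "pos")
  expect_true(npos >= 30 && npos <= 70)   # binomial 3-sigma sanity band

  # separable clouds: linear SVM nails it; no signal: near chance
  ds_sep <- tiny_ds(n = 200, d = 5, sep = 6, seed = 2)
  cc <- evaluate_params(classifier_spec("svm"), c(cost = 1), ds_sep,
                        cv_config(shuffle_seed = 1), seed = 1)
  expect_gte(primary_objectives(cc)["PAC"], 0.95)
  ds_null <- tiny_ds(n = 200, d = 5, sep = 0, seed = 2)
  cc0 <- evaluate_params(classifier_spec("svm"), c(cost = 1), ds_null,
                         cv_config(shuffle_seed = 1), seed = 1)
  pac0 <- primary_objectives(cc0)["PAC"]
  expect_true(pac0 >= 0.35 && pac0 <= 0.65)

  # missingness rate lands near its target
  dm <- make_synthetic(synthetic_spec(200, 10, missing_rate = 0.2, seed = 4))
  expect_equal(mean(dm$missing_mask), 0.2, tolerance = 0.2)
})
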