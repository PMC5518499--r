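# HIS runs in tests use reduced evolver budgets and MLP epochs to stay fast;
# thresholds and seeds are untouched.

test_that("evolver = none equals a single default-parameter evaluation", {
  ds <- tiny_ds(n = 80, d = 4, sep = 2, seed = 15)
  cfg <- his_config("svm", "none", seed = 9)
  r <- run_his(ds, cfg)
  expect_equal(r$n_evaluations, 1L)
  spec <- classifier_spec("svm")
  cv <- cv_config(shuffle_seed = evohis:::derive_seed(9, 11))
  cc <- evaluate_params(spec, c(cost = 1), ds, cv,
                        seed = evohis:::derive_seed(9, 53))
  expect_equal(r$best_objectives, primary_objectives(cc))
  expect_equal(r$best_Z, scalarize(primary_objectives(cc), r$config$weights))
})

test_that("run_his is deterministic and consistent: best_Z, bounds, archive", {
  ds <- make_synthetic(synthetic_spec(80, 4, class_separation = 3,
                                      missing_rate = 0.05, seed = 16))
  cfg <- his_config("svm", "pso", evolver_cfg = small_budget(), seed = 4)
  r1 <- run_his(ds, cfg)
  r2 <- run_his(ds, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$best_Z, scalarize(r1$best_objectives, cfg$weights))
  expect_true(all(r1$best_params >= 0 & r1$best_params <= 1))
  expect_true(all(r1$evaluation_archive$cost >= 0 & r1$evaluation_archive$cost <= 1))
  expect_true(is.finite(r1$gd) && r1$gd >= 0)
  expect_true(is.finite(r1$sp) && r1$sp >= 0)
  # archive best matches reported best
  expect_equal(r1$best_Z, max(r1$evaluation_archive$Z), tolerance = 1e-12)
})

test_that("separable data: every HIS variant reaches near-perfect fitness", {
  ds <- tiny_ds(n = 120, d = 5, sep = 6, seed = 17)
  for (clf in c("svm", "mlp")) {
    r <- run_his(ds, his_config(clf, "pso", evolver_cfg = small_budget(4, 2),
                                seed = 2, epochs = 80))
    expect_gte(r$best_Z, 0.95)
  }
})

test_that("evolved runs weakly dominate the basic run under shared folds", {
  ds <- make_synthetic(synthetic_spec(200, 4, class_separation = 2,
                                      positive_fraction = 0.8, seed = 18))
  basic <- run_his(ds, his_config("svm", "none", seed = 3))
  for (evo in c("pso", "gsa", "fa")) {
    r <- run_his(ds, his_config("svm", evo, evolver_cfg = small_budget(4, 2),
                                seed = 3))
    expect_gte(r$best_Z, basic$best_Z)
  }
})

test_that("run_grid yields 16 deterministic cells in the documented order", {
  ds <- tiny_ds(n = 60, d = 3, sep = 4, seed = 19)
  cfg <- his_config(evolver_cfg = small_budget(3, 2), seed = 7, epochs = 40)
  g <- run_grid(ds, cfg)
  expect_length(g, 16L)
  expect_true(all(vapply(g, inherits, TRUE, "evohis_his_result")))
  expect_equal(names(g)[1:4], c("SVM", "SVM-R", "PSVM", "PSVM-R"))
  expect_equal(names(g)[9:12], c("MLP", "MLP-R", "PMLP", "PMLP-R"))
  # the two basic no-resample cells replicate the plain evaluation procedure
  expect_equal(g$SVM$n_evaluations, 1L)
  expect_equal(g$MLP$n_evaluations, 1L)
  g2 <- run_grid(ds, cfg)
  expect_identical(g, g2)
  expect_true(all(vapply(g, function(r) is.finite(r$gd) && r$gd >= 0, TRUE)))
  expect_true(all(vapply(g, function(r) is.finite(r$sp) && r$sp >= 0, TRUE)))
})

test_that("select_best maximizes Z with documented tie-breaks", {
  ds <- tiny_ds(n = 60, d = 3, sep = 4, seed = 20)
  r1 <- run_his(ds, his_config("svm", "none", seed = 1))
  expect_identical(select_best(list(r1)), r1)
  r2 <- r1; r2$best_Z <- r1$best_Z - 0.1
  expect_identical(select_best(list(r2, r1)), r1)
  # exact Z tie broken by PAC
  r3 <- r1; r3$best_objectives["PAC"] <- r1$best_objectives["PAC"] - 0.01
  expect_identical(select_best(list(r3, r1)), r1)
  expect_error(select_best(list()), class = "evohis_empty_results")
})

test_that("stage errors are annotated and grid cells fail independently", {
  bad <- evohis_dataset(cbind(a = rep(NA_real_, 4), b = c(1, 2, 3, 4)),
                        c("p", "p", "n", "n"), "p")
  err <- tryCatch(run_his(bad, his_config("svm", "none")), error = function(e) e)
  expect_match(conditionMessage(err), "impute")
})

test_that("the CLI writes run artifacts and a synthetic CSV round-trips", {
  out <- file.path(tempdir(), "evohis-cli-test")
  csv <- file.path(out, "synth.csv")
  dir.create(out, showWarnings = FALSE)
  evohis_cli(c("synth", "--n", "60", "--d", "3", "--sep", "5",
               "--seed", "4", "--out", csv))
  expect_true(file.exists(csv))
  ds <- load_dataset(csv, "csv", label_column = "class", positive_label = "pos")
  expect_equal(dim(ds), c(60L, 3L))
  run_dir <- file.path(out, "run")
  evohis_cli(c("run", "--data", csv, "--evolver", "pso", "--agents", "3",
               "--iters", "2", "--seed", "1", "--out", run_dir))
  expect_true(file.exists(file.path(run_dir, "run.json")))
  expect_true(file.exists(file.path(run_dir, "run_archive.csv")))
  rec <- jsonlite::read_json(file.path(run_dir, "run.json"))
  expect_equal(rec$config$evolver, "pso")
  expect_true(rec$best_Z >= 0 && rec$best_Z <= 1)
})
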