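# Hybrid intelligent system orchestration: preprocessing -> optional
# supervised resampling -> evolver-driven hyperparameter search over the
# chosen classifier, fitness = weighted (PAC, SPY, SEY) under stratified CV.

# deterministic sub-seed fan-out from one master seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483646 + 1)
}

#' Configuration of one hybrid-intelligent-system run
#'
#' A run is one cell of the (classifier x evolver x resampling) design:
#' `evolver = "none"` evaluates the classifier once at its default
#' hyperparameters (the "basic" rows of the result tables); otherwise the
#' chosen metaheuristic searches the bounded hyperparameter box.
#'
#' One master `seed` fans out deterministically to fold shuffling,
#' resampling, classifier training and the evolver, so a run is
#' bit-reproducible. The evolver's initial population always contains the
#' classifier's default parameter vector, so an evolved run can never score
#' below the basic run under the same folds.
#'
#' @param classifier `"svm"` or `"mlp"`.
#' @param evolver `"none"`, `"pso"`, `"gsa"` or `"fa"`.
#' @param resample apply supervised instance resampling before CV.
#' @param weights an [objective_weights()] (default 0.95/0.025/0.025).
#' @param cv a [cv_config()]; its `shuffle_seed` is overridden by the fan-out.
#' @param evolver_cfg an [evolver_config()] (default 20 agents x 50 iterations).
#' @param seed master seed.
#' @param resample_bias,resample_size bias-to-uniform and size percent passed
#'   to [supervised_resample()].
#' @param kernel,gamma,epochs fixed classifier settings (see
#'   [classifier_spec()]).
#' @return An object of class `evohis_his_config`.
#' @export
his_config <- function(classifier = c("svm", "mlp"),
                       evolver = c("pso", "gsa", "fa", "none"),
                       resample = FALSE, weights = objective_weights(),
                       cv = cv_config(), evolver_cfg = evolver_config(),
                       seed = 1L, resample_bias = 0, resample_size = 100,
                       kernel = "linear", gamma = 1, epochs = 500L) {
  structure(list(classifier = match.arg(classifier),
                 evolver = match.arg(evolver),
                 resample = isTRUE(resample), weights = weights, cv = cv,
                 evolver_cfg = evolver_cfg, seed = as.integer(seed),
                 resample_bias = resample_bias, resample_size = resample_size,
                 kernel = kernel, gamma = gamma, epochs = as.integer(epochs)),
            class = "evohis_his_config")
}

cell_name <- function(cfg) {
  base <- toupper(cfg$classifier)
  prefix <- switch(cfg$evolver, none = "", pso = "P", gsa = "G", fa = "F")
  paste0(prefix, base, if (cfg$resample) "-R" else "")
}

#' Run one hybrid intelligent system
#'
#' Pipeline: impute missing values, min-max normalize, optionally resample,
#' then maximize `Z = w1*PAC + w2*SPY + w3*SEY` (each point measured by
#' pooled stratified 10-fold CV) over the classifier's hyperparameter box
#' with the configured evolver. Every fitness evaluation is archived with its
#' full objective triple for the Pareto metrics.
#'
#' @param ds an [evohis_dataset()], raw or preprocessed.
#' @param cfg an [his_config()].
#' @return An object of class `evohis_his_result`: `cell` (configuration
#'   name), `config`, `best_params`, `best_objectives` (PAC/SEY/SPY),
#'   `best_Z`, `confusion`, `secondary` metrics, `evaluation_archive`,
#'   `gd`, `sp` (against the run's own nondominated front; [run_grid()]
#'   recomputes them against the run-set reference front), `n_evaluations`.
#' @export
run_his <- function(ds, cfg = his_config()) {
  stopifnot(inherits(ds, "evohis_dataset"), inherits(cfg, "evohis_his_config"))
  stage <- function(what, expr) {
    tryCatch(expr, evohis_error = function(e) {
      stop_evohis(class(e)[1L], "[stage %s] %s", what, conditionMessage(e))
    })
  }
  ds <- stage("impute", impute_missing(ds))
  ds <- stage("normalize", minmax_normalize(ds))
  if (cfg$resample)
    ds <- stage("resample",
                supervised_resample(ds, seed = derive_seed(cfg$seed, 23),
                                    bias_to_uniform = cfg$resample_bias,
                                    size_percent = cfg$resample_size))
  spec <- classifier_spec(cfg$classifier, kernel = cfg$kernel,
                          gamma = cfg$gamma, epochs = cfg$epochs)
  cv <- cfg$cv
  cv$shuffle_seed <- derive_seed(cfg$seed, 11)
  train_seed <- derive_seed(cfg$seed, 53)
  fitness <- function(pos) {
    cc <- evaluate_params(spec, pos, ds, cv, seed = train_seed)
    obj <- primary_objectives(cc)
    z <- scalarize(obj, cfg$weights)
    attr(z, "objectives") <- obj
    z
  }
  defaults <- default_params(spec)
  if (cfg$evolver == "none") {
    z <- fitness(defaults)
    arch <- new_archiver(names(defaults))
    archive_eval(arch, 0L, 1L, defaults, z)
    opt <- finish_result(unname(defaults), as.numeric(z), as.numeric(z), arch,
                         list(names = names(defaults)))
  } else {
    ecfg <- cfg$evolver_cfg
    ecfg$seed <- derive_seed(cfg$seed, 37)
    ecfg$init_positions <- matrix(defaults, nrow = 1L)
    optimizer <- switch(cfg$evolver, pso = pso_optimize, gsa = gsa_optimize,
                        fa = fa_optimize)
    opt <- stage("evolve", optimizer(fitness, spec$tunables, ecfg))
  }
  best_params <- opt$best_position
  cc <- evaluate_params(spec, best_params, ds, cv, seed = train_seed)
  obj <- primary_objectives(cc)
  front <- nondominated(opt$evaluation_archive[, c("PAC", "SEY", "SPY"), drop = FALSE])
  structure(list(
    cell = cell_name(cfg), config = cfg,
    best_params = best_params, best_objectives = obj,
    best_Z = scalarize(obj, cfg$weights),
    confusion = cc, secondary = secondary_metrics(cc),
    evaluation_archive = opt$evaluation_archive,
    fitness_history = opt$fitness_history,
    gd = generational_distance(front, front),
    sp = if (nrow(front) >= 2L) spacing(front) else 0,
    n_evaluations = nrow(opt$evaluation_archive)
  ), class = "evohis_his_result")
}

#' @export
print.evohis_his_result <- function(x, ...) {
  cat(sprintf("<HIS %s> Z = %.4f | PAC %.4f SEY %.4f SPY %.4f | params: %s\n",
              x$cell, x$best_Z, x$best_objectives["PAC"],
              x$best_objectives["SEY"], x$best_objectives["SPY"],
              paste(sprintf("%s=%.4f", names(x$best_params), x$best_params),
                    collapse = ", ")))
  invisible(x)
}

#' Run the full 16-configuration grid
#'
#' The Cartesian design \{svm, mlp\} x \{none, pso, gsa, fa\} x \{no
#' resampling, resampling\}, in that nesting order (classifier outermost,
#' resampling innermost), for a total of 16 runs: per classifier, one basic
#' run and three evolved runs, each with and without resampling. All cells
#' share the master seed, so folds, training seeds and the resampled data are
#' identical across cells and the basic/evolved comparison is paired.
#' After the grid completes, each cell's `gd`/`sp` are recomputed against the
#' reference front built from all cells' archives.
#'
#' @param ds an [evohis_dataset()].
#' @param base_cfg an [his_config()] providing everything except `classifier`,
#'   `evolver` and `resample`.
#' @return List of 16 `evohis_his_result` (a failed cell is recorded as a
#'   condition object in its slot), with attribute `reference_front`.
#' @export
run_grid <- function(ds, base_cfg = his_config()) {
  cells <- expand.grid(resample = c(FALSE, TRUE),
                       evolver = c("none", "pso", "gsa", "fa"),
                       classifier = c("svm", "mlp"),
                       stringsAsFactors = FALSE)
  # documented order: classifier, then evolver, then resampling
  cells <- cells[, c("classifier", "evolver", "resample")]
  results <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cfg <- base_cfg
    cfg$classifier <- cells$classifier[k]
    cfg$evolver <- cells$evolver[k]
    cfg$resample <- cells$resample[k]
    results[[k]] <- tryCatch(run_his(ds, cfg), error = function(e) e)
    names(results)[k] <- if (inherits(results[[k]], "evohis_his_result"))
      results[[k]]$cell
    else paste0(cells$classifier[k], "_", cells$evolver[k],
                if (cells$resample[k]) "_rs" else "")
  }
  ok <- vapply(results, inherits, TRUE, "evohis_his_result")
  if (any(ok)) {
    ref <- build_reference_front(
      lapply(results[ok], function(r)
        r$evaluation_archive[, c("PAC", "SEY", "SPY"), drop = FALSE]))
    for (k in which(ok)) {
      Q <- nondominated(results[[k]]$evaluation_archive[, c("PAC", "SEY", "SPY"),
                                                        drop = FALSE])
      nf <- normalize_front(Q, ref)
      results[[k]]$gd <- generational_distance(nf$Q, nf$reference)
      results[[k]]$sp <- if (nrow(nf$Q) >= 2L) spacing(nf$Q) else 0
    }
    attr(results, "reference_front") <- ref
  }
  results
}

#' Select the best hybrid system from a set of results
#'
#' Maximal scalarized fitness `best_Z`; ties broken by higher PAC, then by
#' configuration order (svm before mlp; none, pso, gsa, fa; no resampling
#' before resampling).
#'
#' @param results list of `evohis_his_result` (condition objects from failed
#'   grid cells are skipped).
#' @return The winning `evohis_his_result`.
#' @export
select_best <- function(results) {
  results <- Filter(function(r) inherits(r, "evohis_his_result"), results)
  if (length(results) == 0L)
    stop_evohis("evohis_empty_results", "no successful results to select from")
  z <- vapply(results, `[[`, 0, "best_Z")
  pac <- vapply(results, function(r) unname(r$best_objectives["PAC"]), 0)
  clf <- match(vapply(results, function(r) r$config$classifier, ""), c("svm", "mlp"))
  evo <- match(vapply(results, function(r) r$config$evolver, ""),
               c("none", "pso", "gsa", "fa"))
  rs <- vapply(results, function(r) r$config$resample, TRUE)
  ord <- order(-z, -pac, clf, evo, rs)
  results[[ord[1L]]]
}
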