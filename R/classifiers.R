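#' Classifier specification
#'
#' Declares which classifier to tune and its search surface. The evolvable
#' hyperparameters are bounded to \[0, 1\]: the SVM soft-margin cost `C`
#' (values at 0 are lifted to 1e-6 to keep the solver defined), and the MLP
#' learning rate and momentum. Everything else is a fixed setting.
#'
#' The MLP is a three-layer network: input size = number of (one-hot encoded)
#' features, one hidden layer sized as the rounded average of input and output
#' layer sizes, output layer = 2 (one unit per class), logistic activations.
#'
#' @param kind `"svm"` or `"mlp"`.
#' @param kernel SVM kernel, `"linear"` (default) or `"rbf"`.
#' @param gamma RBF kernel width (fixed; only the cost is evolved).
#' @param epochs MLP training epochs (default 500, the Weka default budget).
#' @return An object of class `evohis_classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "mlp"), kernel = c("linear", "rbf"),
                            gamma = 1, epochs = 500L) {
  kind <- match.arg(kind); kernel <- match.arg(kernel)
  tunables <- if (kind == "svm") {
    list(parameter_spec("cost", 0, 1))
  } else {
    list(parameter_spec("learning_rate", 0, 1), parameter_spec("momentum", 0, 1))
  }
  structure(list(kind = kind, tunables = tunables,
                 fixed_settings = list(kernel = kernel, gamma = gamma,
                                       epochs = as.integer(epochs))),
            class = "evohis_classifier_spec")
}

# default hyperparameters: Weka SMO default C = 1; Weka MultilayerPerceptron
# defaults learning rate 0.3, momentum 0.2
default_params <- function(spec) {
  if (spec$kind == "svm") c(cost = 1) else c(learning_rate = 0.3, momentum = 0.2)
}

#' Cross-validation configuration
#'
#' @param n_folds number of folds (default 10).
#' @param shuffle_seed seed controlling fold assignment; folds depend only on
#'   (n, labels, shuffle_seed).
#' @param stratified keep per-fold class proportions within one instance of
#'   the global proportions (default TRUE).
#' @return An object of class `evohis_cv_config`.
#' @export
cv_config <- function(n_folds = 10L, shuffle_seed = 1L, stratified = TRUE) {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds),
                 shuffle_seed = as.integer(shuffle_seed),
                 stratified = isTRUE(stratified)),
            class = "evohis_cv_config")
}

#' Stratified fold assignment
#'
#' Shuffles instances within each class and deals them round-robin over the
#' folds, so each fold's positive fraction is within one instance of the
#' global fraction.
#'
#' @param labels two-level factor of class labels.
#' @param n_folds number of folds.
#' @param seed shuffle seed.
#' @param stratified if FALSE, plain shuffled assignment.
#' @return Integer vector of fold ids in `1:n_folds`.
#' @export
stratified_folds <- function(labels, n_folds, seed, stratified = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  fold
}

# one-hot encode nominal features; numeric features pass through.
# Encoding uses the dataset-level nominal level sets, so every fold of the
# same dataset maps to the same columns.
encode_features <- function(ds) {
  X <- ds$features
  if (!any(ds$feature_kinds == "nominal")) return(X)
  cols <- list()
  for (j in seq_len(ncol(X))) {
    nm <- ds$feature_names[j]
    if (ds$feature_kinds[j] == "numeric") {
      cols[[nm]] <- X[, j, drop = FALSE]
    } else {
      levs <- ds$nominal_levels[[nm]] %||% seq_len(max(X[, j]))
      oh <- matrix(0, nrow(X), length(levs),
                   dimnames = list(NULL, paste(nm, seq_along(levs), sep = "_")))
      oh[cbind(seq_len(nrow(X)), X[, j])] <- 1
      cols[[nm]] <- oh
    }
  }
  do.call(cbind, cols)
}

check_bounds <- function(spec, params) {
  nms <- vapply(spec$tunables, `[[`, "", "name")
  if (length(params) != length(nms))
    stop_evohis("evohis_bound_violation", "expected %d parameters (%s), got %d",
                length(nms), paste(nms, collapse = ", "), length(params))
  for (k in seq_along(nms)) {
    p <- unname(params[k]); ps <- spec$tunables[[k]]
    if (!is.finite(p) || p < ps$lower || p > ps$upper)
      stop_evohis("evohis_bound_violation", "parameter '%s'=%g outside [%g, %g]",
                  ps$name, p, ps$lower, ps$upper)
  }
  stats::setNames(as.numeric(params), nms)
}

#' Train a classifier at given hyperparameters
#'
#' @param spec a [classifier_spec()].
#' @param params numeric vector of tunables in spec order (`cost` for SVM;
#'   `learning_rate`, `momentum` for MLP), each within its bounds.
#' @param train an [evohis_dataset()] (preprocessed; both classes present).
#' @param seed training seed (SVM sweep order / MLP weight init).
#' @return An object of class `evohis_model` with a [predict][predict.evohis_model] method.
#' @export
train_classifier <- function(spec, params, train, seed = 1L) {
  stopifnot(inherits(spec, "evohis_classifier_spec"), inherits(train, "evohis_dataset"))
  params <- check_bounds(spec, params)
  if (length(unique(train$labels)) < 2L)
    stop_evohis("evohis_degenerate_fold", "training data contains a single class")
  X <- encode_features(train)
  pos <- levels(train$labels)[1L]
  y <- ifelse(train$labels == pos, 1, -1)
  fit <- withr::with_seed(seed, {
    if (spec$kind == "svm") {
      C <- max(params[["cost"]], 1e-6)
      if (spec$fixed_settings$kernel == "linear") {
        m <- .svm_dcd_linear(X, y, C, 1e-3, 1000L)
        list(type = "svm_linear", w = m$w, b = m$b)
      } else {
        K <- rbf_kernel(X, X, spec$fixed_settings$gamma)
        alpha <- .svm_dcd_kernel(K, y, C, 1e-3, 1000L)
        list(type = "svm_rbf", alpha = alpha, y = y, Xtr = X,
             gamma = spec$fixed_settings$gamma)
      }
    } else {
      h <- max(1L, as.integer(round((ncol(X) + 2L) / 2)))
      Tm <- cbind(as.numeric(y == 1), as.numeric(y == -1))
      m <- .mlp_train(X, Tm, h, params[["learning_rate"]], params[["momentum"]],
                      spec$fixed_settings$epochs)
      list(type = "mlp", W1 = m$W1, W2 = m$W2)
    }
  })
  structure(list(spec = spec, params = params, fit = fit,
                 levels = levels(train$labels)),
            class = "evohis_model")
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  exp(-gamma * pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0))
}

#' Predict class labels
#'
#' @param object an `evohis_model` from [train_classifier()].
#' @param newdata an [evohis_dataset()] or pre-encoded numeric matrix.
#' @param ... unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.evohis_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "evohis_dataset")) encode_features(newdata) else as.matrix(newdata)
  f <- object$fit
  score <- switch(f$type,
    svm_linear = drop(X %*% f$w) + f$b,
    svm_rbf = drop(rbf_kernel(X, f$Xtr, f$gamma) %*% (f$alpha * f$y)) +
              sum(f$alpha * f$y),
    mlp = { o <- .mlp_forward(X, f$W1, f$W2); o[, 1L] - o[, 2L] })
  factor(ifelse(score >= 0, object$levels[1L], object$levels[2L]),
         levels = object$levels)
}

#' Cross-validated evaluation of one hyperparameter vector
#'
#' Trains on each stratified fold's complement, predicts the held-out fold
#' and pools the confusion counts over folds, so `TP + FN = m1` and
#' `TN + FP = m2` hold exactly for the full dataset.
#'
#' @param spec a [classifier_spec()].
#' @param params hyperparameter vector (see [train_classifier()]).
#' @param ds a preprocessed [evohis_dataset()].
#' @param cv a [cv_config()]; fold assignment uses `cv$shuffle_seed`.
#' @param seed training seed, fanned out per fold.
#' @return Pooled `evohis_confusion` counts.
#' @export
evaluate_params <- function(spec, params, ds, cv = cv_config(), seed = 1L) {
  stopifnot(inherits(ds, "evohis_dataset"), inherits(cv, "evohis_cv_config"))
  if (cv$stratified && cv$n_folds > min(n_positive(ds), n_negative(ds)))
    stop_evohis("evohis_degenerate_fold",
                "n_folds = %d exceeds the minority class size %d",
                cv$n_folds, min(n_positive(ds), n_negative(ds)))
  fold <- stratified_folds(ds$labels, cv$n_folds, cv$shuffle_seed, cv$stratified)
  ccs <- lapply(seq_len(cv$n_folds), function(k) {
    tr <- ds_subset(ds, fold != k)
    te <- ds_subset(ds, fold == k)
    model <- train_classifier(spec, params, tr, seed = seed + k)
    confusion_counts(te$labels, predict(model, te))
  })
  sum_confusion(ccs)
}
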