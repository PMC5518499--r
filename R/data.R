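#' Binary classification dataset container
#'
#' Lightweight container for a tabular binary-classification dataset: a
#' numeric feature matrix (nominal features integer-coded), a two-class label
#' factor whose first level is the positive class, per-feature kind flags and
#' a missingness mask. All preprocessing and evaluation functions in the
#' package operate on this class.
#'
#' @param features numeric matrix, n instances x d features. Nominal features
#'   are integer level codes (1-based).
#' @param labels vector of length n with exactly two distinct values.
#' @param positive the label value treated as the positive class (cases).
#' @param feature_kinds character vector of length d, `"numeric"` or
#'   `"nominal"`. Defaults to all numeric.
#' @param nominal_levels named list mapping nominal feature names to their
#'   level strings (used for one-hot encoding and ARFF round-trips).
#' @param missing_mask logical n x d matrix; defaults to `is.na(features)`.
#' @return An object of class `evohis_dataset` with elements `features`,
#'   `labels`, `feature_names`, `feature_kinds`, `missing_mask`,
#'   `nominal_levels`.
#' @export
evohis_dataset <- function(features, labels, positive = NULL,
                           feature_kinds = NULL, nominal_levels = list(),
                           missing_mask = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features); d <- ncol(features)
  if (n < 2L || d < 1L)
    stop_evohis("evohis_bad_shape", "need n >= 2 instances and d >= 1 features (got %d x %d)", n, d)
  if (length(labels) != n)
    stop_evohis("evohis_bad_shape", "labels length %d != n = %d", length(labels), n)
  uv <- unique(as.character(labels))
  uv <- uv[!is.na(uv)]
  if (length(uv) != 2L)
    stop_evohis("evohis_not_binary", "labels must take exactly 2 values, found %d", length(uv))
  if (is.null(positive)) positive <- sort(uv)[1L]
  positive <- as.character(positive)
  if (!positive %in% uv)
    stop_evohis("evohis_not_binary", "positive label '%s' not present in labels", positive)
  negative <- setdiff(uv, positive)
  labels <- factor(as.character(labels), levels = c(positive, negative))
  if (any(table(labels) == 0L))
    stop_evohis("evohis_not_binary", "each class needs at least one instance")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(d))
  feature_kinds <- feature_kinds %||% rep("numeric", d)
  stopifnot(length(feature_kinds) == d, all(feature_kinds %in% c("numeric", "nominal")))
  missing_mask <- missing_mask %||% is.na(features)
  missing_mask <- matrix(as.logical(missing_mask), n, d)
  structure(
    list(features = features, labels = labels,
         feature_names = colnames(features), feature_kinds = feature_kinds,
         missing_mask = missing_mask, nominal_levels = nominal_levels),
    class = "evohis_dataset"
  )
}

#' @export
print.evohis_dataset <- function(x, ...) {
  cat(sprintf("<evohis_dataset> %d instances x %d features (%d nominal), %d/%d pos/neg, %d missing cells\n",
              nrow(x$features), ncol(x$features),
              sum(x$feature_kinds == "nominal"),
              sum(x$labels == levels(x$labels)[1L]),
              sum(x$labels == levels(x$labels)[2L]),
              sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.evohis_dataset <- function(x) dim(x$features)

# number of positive (m1) and negative (m2) instances
n_positive <- function(ds) sum(ds$labels == levels(ds$labels)[1L])
n_negative <- function(ds) sum(ds$labels == levels(ds$labels)[2L])

# row subset preserving all metadata
ds_subset <- function(ds, idx) {
  out <- ds
  out$features <- ds$features[idx, , drop = FALSE]
  out$labels <- ds$labels[idx]
  out$missing_mask <- ds$missing_mask[idx, , drop = FALSE]
  out
}

#' Load a tabular binary dataset from CSV or ARFF
#'
#' CSV files need a header row; empty strings, `"?"` and `"NA"` are missing.
#' ARFF files follow the standard Weka dialect (`@attribute` declarations,
#' `?` missing); nominal attributes keep their declared level order.
#' Non-numeric CSV columns are treated as nominal and integer-coded.
#'
#' @param path file path.
#' @param format `"csv"` or `"arff"`.
#' @param label_column name of the class column.
#' @param positive_label value of `label_column` mapped to the positive class.
#' @return [evohis_dataset()] with missing cells flagged in `missing_mask`.
#' @export
load_dataset <- function(path, format = c("csv", "arff"),
                         label_column, positive_label) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_evohis("evohis_missing_file", "no such file: %s", path)
  if (format == "csv") {
    df <- read.csv(path, na.strings = c("", "?", "NA"), check.names = FALSE,
                   stringsAsFactors = FALSE)
    declared <- NULL
  } else {
    parsed <- read_arff(path)
    df <- parsed$data
    declared <- parsed$levels   # named list: nominal attr -> level strings
  }
  if (!label_column %in% names(df))
    stop_evohis("evohis_missing_label_column", "label column '%s' not found", label_column)
  y <- df[[label_column]]
  uv <- unique(as.character(y[!is.na(y)]))
  if (length(uv) != 2L)
    stop_evohis("evohis_not_binary",
                "label column '%s' has %d distinct values, need exactly 2",
                label_column, length(uv))
  xdf <- df[setdiff(names(df), label_column)]
  kinds <- character(ncol(xdf)); nominal_levels <- list()
  X <- matrix(NA_real_, nrow(xdf), ncol(xdf),
              dimnames = list(NULL, names(xdf)))
  for (j in seq_along(xdf)) {
    col <- xdf[[j]]; nm <- names(xdf)[j]
    if (is.numeric(col) && is.null(declared[[nm]])) {
      kinds[j] <- "numeric"
      X[, j] <- as.numeric(col)
    } else {
      kinds[j] <- "nominal"
      levs <- declared[[nm]] %||% sort(unique(as.character(col[!is.na(col)])))
      nominal_levels[[nm]] <- levs
      X[, j] <- as.integer(factor(as.character(col), levels = levs))
    }
  }
  evohis_dataset(X, y, positive = as.character(positive_label),
                 feature_kinds = kinds, nominal_levels = nominal_levels)
}

# minimal ARFF reader (standard Weka dialect, dense rows only); no ARFF
# parser is available among the package's dependencies
read_arff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  attr_lines <- grep("^@attribute", lines, ignore.case = TRUE, value = TRUE)
  data_at <- grep("^@data", lines, ignore.case = TRUE)
  if (length(attr_lines) == 0L || length(data_at) == 0L)
    stop_evohis("evohis_bad_arff", "not a valid ARFF file: %s", path)
  names_ <- character(0); levels_ <- list(); numeric_ <- logical(0)
  for (al in attr_lines) {
    body <- trimws(sub("^@attribute\\s+", "", al, ignore.case = TRUE))
    if (startsWith(body, "'") || startsWith(body, "\"")) {
      q <- substr(body, 1, 1)
      end <- regexpr(q, substr(body, 2, nchar(body)), fixed = TRUE)
      nm <- substr(body, 2, end); rest <- trimws(substr(body, end + 2, nchar(body)))
    } else {
      sp <- regexpr("\\s", body)
      nm <- substr(body, 1, sp - 1); rest <- trimws(substr(body, sp + 1, nchar(body)))
    }
    names_ <- c(names_, nm)
    if (startsWith(rest, "{")) {
      inner <- sub("\\}\\s*$", "", sub("^\\{", "", rest))
      levs <- trimws(strsplit(inner, ",")[[1]])
      levs <- gsub("^['\"]|['\"]$", "", levs)
      levels_[[nm]] <- levs
      numeric_ <- c(numeric_, FALSE)
    } else {
      numeric_ <- c(numeric_, grepl("^(numeric|real|integer)", rest, ignore.case = TRUE))
    }
  }
  rows <- lines[(data_at[1L] + 1L):length(lines)]
  cells <- strsplit(rows, ",")
  df <- as.data.frame(matrix(NA_character_, length(rows), length(names_)),
                      stringsAsFactors = FALSE)
  names(df) <- names_
  for (i in seq_along(cells)) {
    v <- gsub("^['\"]|['\"]$", "", trimws(cells[[i]]))
    v[v == "?"] <- NA_character_
    df[i, ] <- as.list(v)
  }
  for (j in seq_along(df)) if (numeric_[j]) df[[j]] <- as.numeric(df[[j]])
  list(data = df, levels = levels_)
}

#' Fill missing values with per-feature mode (nominal) or mean (numeric)
#'
#' Numeric features receive the mean of their observed values, nominal
#' features the most frequent observed level (ties broken toward the lowest
#' level code). Observed cells are untouched.
#'
#' @param ds an [evohis_dataset()].
#' @return The dataset with `missing_mask` all `FALSE`.
#' @export
impute_missing <- function(ds) {
  stopifnot(inherits(ds, "evohis_dataset"))
  X <- ds$features; M <- ds$missing_mask
  for (j in seq_len(ncol(X))) {
    miss <- M[, j]
    if (!any(miss)) next
    if (all(miss))
      stop_evohis("evohis_unimputable_feature",
                  "feature '%s' is entirely missing", ds$feature_names[j])
    obs <- X[!miss, j]
    fill <- if (ds$feature_kinds[j] == "nominal") {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])   # which.max -> lowest code on ties
    } else mean(obs)
    X[miss, j] <- fill
  }
  ds$features <- X
  ds$missing_mask[] <- FALSE
  ds
}

#' Min-max normalize numeric features to [0, 1]
#'
#' Each numeric feature is mapped by `(x - min) / (max - min)`; constant
#' features map to 0 (Weka convention, avoids 0/0). Nominal level codes and
#' labels are untouched. Idempotent.
#'
#' @param ds an [evohis_dataset()] without missing values.
#' @return The normalized dataset.
#' @export
minmax_normalize <- function(ds) {
  stopifnot(inherits(ds, "evohis_dataset"))
  if (any(ds$missing_mask))
    stop_evohis("evohis_has_missing", "impute missing values before normalizing")
  X <- ds$features
  for (j in which(ds$feature_kinds == "numeric")) {
    rng <- range(X[, j])
    X[, j] <- if (rng[1] == rng[2]) 0 else (X[, j] - rng[1]) / (rng[2] - rng[1])
  }
  ds$features <- X
  ds
}

#' Supervised instance resampling (Weka Resample semantics)
#'
#' Draws `round(n * size_percent / 100)` instances with replacement. The
#' probability of drawing from a class interpolates linearly between the
#' empirical class distribution (`bias_to_uniform = 0`) and the uniform
#' distribution over the two classes (`bias_to_uniform = 1`); within a class,
#' instances are drawn uniformly. Deterministic for a fixed seed.
#'
#' @param ds an [evohis_dataset()], typically preprocessed.
#' @param seed integer RNG seed.
#' @param bias_to_uniform real in \[0, 1\].
#' @param size_percent output size as a percentage of n (default 100).
#' @return A resampled [evohis_dataset()].
#' @export
supervised_resample <- function(ds, seed, bias_to_uniform = 0, size_percent = 100) {
  stopifnot(inherits(ds, "evohis_dataset"),
            bias_to_uniform >= 0, bias_to_uniform <= 1, size_percent > 0)
  n <- nrow(ds$features)
  t_out <- round(n * size_percent / 100)
  if (t_out < 1L)
    stop_evohis("evohis_empty_resample", "requested resample size is 0")
  pos_lab <- levels(ds$labels)[1L]
  pos_idx <- which(ds$labels == pos_lab)
  neg_idx <- which(ds$labels != pos_lab)
  p_emp <- length(pos_idx) / n
  p_pos <- (1 - bias_to_uniform) * p_emp + bias_to_uniform * 0.5
  idx <- withr::with_seed(seed, {
    take_pos <- runif(t_out) < p_pos
    out <- integer(t_out)
    out[take_pos] <- pos_idx[sample.int(length(pos_idx), sum(take_pos), replace = TRUE)]
    out[!take_pos] <- neg_idx[sample.int(length(neg_idx), sum(!take_pos), replace = TRUE)]
    out
  })
  ds_subset(ds, idx)
}

#' Specification for the synthetic binary dataset generator
#'
#' The generator emulates the structure of small UCI-style clinical tables:
#' two Gaussian class-conditional clouds in d dimensions whose means are
#' `class_separation` within-class standard deviations apart along a random
#' unit direction, with optional label noise and missingness.
#'
#' @param n_instances,n_features dataset shape.
#' @param class_separation nonnegative; distance between class means in units
#'   of the within-class standard deviation (0 = no signal).
#' @param positive_fraction expected fraction of positives, in (0, 1).
#' @param label_noise per-label flip probability, in \[0, 1).
#' @param missing_rate per-cell masking probability, in \[0, 1).
#' @param seed integer RNG seed.
#' @return An object of class `evohis_synthetic_spec`.
#' @export
synthetic_spec <- function(n_instances = 200L, n_features = 5L,
                           class_separation = 2, positive_fraction = 0.5,
                           label_noise = 0, missing_rate = 0, seed = 1L) {
  stopifnot(n_instances >= 2, n_features >= 1, class_separation >= 0,
            positive_fraction > 0, positive_fraction < 1,
            label_noise >= 0, label_noise < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_instances = as.integer(n_instances),
                 n_features = as.integer(n_features),
                 class_separation = class_separation,
                 positive_fraction = positive_fraction,
                 label_noise = label_noise, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "evohis_synthetic_spec")
}

#' Generate a synthetic binary dataset
#'
#' @param spec a [synthetic_spec()].
#' @return An [evohis_dataset()] with labels `"pos"` / `"neg"` (positive class
#'   `"pos"`); bit-reproducible for a fixed `spec$seed`.
#' @export
make_synthetic <- function(spec) {
  stopifnot(inherits(spec, "evohis_synthetic_spec"))
  n <- spec$n_instances; d <- spec$n_features
  withr::with_seed(spec$seed, {
    u <- rnorm(d); u <- u / sqrt(sum(u^2))
    y <- rbinom(n, 1L, spec$positive_fraction)        # 1 = positive
    # guarantee both classes present (binomial support allows 0/n only at
    # negligible probability for the defaults; repair keeps invariants)
    if (all(y == 1L)) y[1L] <- 0L
    if (all(y == 0L)) y[1L] <- 1L
    shift <- spec$class_separation / 2
    X <- matrix(rnorm(n * d), n, d) +
      outer(ifelse(y == 1L, shift, -shift), u)
    if (spec$label_noise > 0) {
      flip <- runif(n) < spec$label_noise
      y[flip] <- 1L - y[flip]
      if (all(y == 1L)) y[1L] <- 0L
      if (all(y == 0L)) y[1L] <- 1L
    }
    mask <- matrix(FALSE, n, d)
    if (spec$missing_rate > 0) {
      mask <- matrix(runif(n * d) < spec$missing_rate, n, d)
      mask[rowSums(!mask) == 0L, 1L] <- FALSE  # keep no row fully missing
      for (j in which(colSums(!mask) == 0L)) mask[1L, j] <- FALSE
      X[mask] <- NA_real_
    }
    colnames(X) <- paste0("f", seq_len(d))
    evohis_dataset(X, ifelse(y == 1L, "pos", "neg"), positive = "pos",
                   missing_mask = mask)
  })
}
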