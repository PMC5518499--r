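#' Confusion counts for a binary classifier
#'
#' Tallies true/false positives and negatives. With `m1` actual positives and
#' `m2` actual negatives, the identities `TP + FN = m1`, `TN + FP = m2` and
#' `TP + TN + FP + FN = N` hold by construction: every instance falls in
#' exactly one cell.
#'
#' @param true_labels,predicted_labels equal-length vectors over the same
#'   two-value alphabet.
#' @param positive the value denoting the positive class; defaults to the
#'   first factor level of `true_labels` (the container convention).
#' @return An object of class `evohis_confusion`: integer TP, TN, FP, FN.
#' @export
confusion_counts <- function(true_labels, predicted_labels, positive = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop_evohis("evohis_length_mismatch", "true (%d) and predicted (%d) lengths differ",
                length(true_labels), length(predicted_labels))
  if (is.null(positive)) {
    if (!is.factor(true_labels))
      stop_evohis("evohis_bad_labels", "supply `positive` when labels are not a factor")
    positive <- levels(true_labels)[1L]
  }
  tl <- as.character(true_labels); pl <- as.character(predicted_labels)
  alphabet <- if (is.factor(true_labels)) levels(true_labels) else unique(c(tl, pl))
  if (length(alphabet) > 2L || !all(pl %in% alphabet) || !all(tl %in% alphabet))
    stop_evohis("evohis_bad_labels", "labels outside the binary alphabet")
  tp <- sum(tl == positive & pl == positive)
  tn <- sum(tl != positive & pl != positive)
  m1 <- sum(tl == positive); m2 <- sum(tl != positive)
  new_confusion(tp, tn, m2 - tn, m1 - tp)
}

new_confusion <- function(TP, TN, FP, FN) {
  structure(list(TP = as.integer(TP), TN = as.integer(TN),
                 FP = as.integer(FP), FN = as.integer(FN)),
            class = "evohis_confusion")
}

#' @export
print.evohis_confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d TN=%d FP=%d FN=%d (N=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

# sum confusion counts across CV folds (pooled counts keep the m1/m2
# identities exact for the full dataset)
sum_confusion <- function(ccs) {
  new_confusion(sum(vapply(ccs, `[[`, 0L, "TP")),
                sum(vapply(ccs, `[[`, 0L, "TN")),
                sum(vapply(ccs, `[[`, 0L, "FP")),
                sum(vapply(ccs, `[[`, 0L, "FN")))
}

#' Primary objectives: accuracy, sensitivity, specificity
#'
#' PAC = (TP + TN) / N, SEY = TP / (TP + FN) (true-positive rate),
#' SPY = TN / (TN + FP) (true-negative rate). Requires at least one actual
#' positive and one actual negative, otherwise SEY or SPY is 0/0.
#'
#' @param cc an `evohis_confusion` (see [confusion_counts()]).
#' @return Named numeric vector `c(PAC =, SEY =, SPY =)`, each in \[0, 1\].
#' @export
primary_objectives <- function(cc) {
  stopifnot(inherits(cc, "evohis_confusion"))
  m1 <- cc$TP + cc$FN; m2 <- cc$TN + cc$FP
  if (m1 == 0L || m2 == 0L)
    stop_evohis("evohis_undefined_objective",
                "sensitivity/specificity undefined: m1=%d, m2=%d", m1, m2)
  c(PAC = (cc$TP + cc$TN) / (m1 + m2), SEY = cc$TP / m1, SPY = cc$TN / m2)
}

#' Objective weights for the scalarized fitness
#'
#' Weights must be nonnegative and sum to 1. The defaults put 95% of the
#' weight on accuracy and split the remaining 5% between specificity and
#' sensitivity, prioritizing prediction accuracy.
#'
#' @param w1,w2,w3 weights for PAC, SPY and SEY respectively.
#' @return Named numeric vector of class `evohis_weights`.
#' @export
objective_weights <- function(w1 = 0.95, w2 = 0.025, w3 = 0.025) {
  w <- c(w1 = w1, w2 = w2, w3 = w3)
  if (any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-12)
    stop_evohis("evohis_bad_weights",
                "weights must lie in [0,1] and sum to 1 (got %s)",
                paste(signif(w, 6), collapse = ", "))
  structure(w, class = "evohis_weights")
}

#' Weighted-sum scalarization of the objective triple
#'
#' Z = w1 * PAC + w2 * SPY + w3 * SEY. A convex combination, so Z lies in
#' \[0, 1\] and is monotone nondecreasing in each objective.
#'
#' @param obj named numeric with components `PAC`, `SEY`, `SPY` (as returned
#'   by [primary_objectives()]).
#' @param w an [objective_weights()] vector.
#' @return Scalar fitness Z.
#' @export
scalarize <- function(obj, w = objective_weights()) {
  if (!inherits(w, "evohis_weights")) w <- do.call(objective_weights, as.list(unname(w)))
  unname(w["w1"] * obj["PAC"] + w["w2"] * obj["SPY"] + w["w3"] * obj["SEY"])
}

#' Class-weighted precision, recall and F-measure
#'
#' Per-class precision/recall/F1 averaged with weights m1/N and m2/N (the
#' summary-row convention of Weka's evaluation output). Under this convention
#' weighted recall equals PAC identically. A per-class metric with a zero
#' denominator contributes 0 and raises a warning.
#'
#' @param cc an `evohis_confusion`.
#' @return Named numeric `c(precision =, recall =, f_measure =)`.
#' @export
secondary_metrics <- function(cc) {
  stopifnot(inherits(cc, "evohis_confusion"))
  m1 <- cc$TP + cc$FN; m2 <- cc$TN + cc$FP; n <- m1 + m2
  safe <- function(num, den, what) {
    if (den == 0) { warning(sprintf("undefined %s (0/0) treated as 0", what)); 0 }
    else num / den
  }
  prec_p <- safe(cc$TP, cc$TP + cc$FP, "positive precision")
  prec_n <- safe(cc$TN, cc$TN + cc$FN, "negative precision")
  rec_p <- safe(cc$TP, m1, "positive recall")
  rec_n <- safe(cc$TN, m2, "negative recall")
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  wp <- m1 / n; wn <- m2 / n
  c(precision = wp * prec_p + wn * prec_n,
    recall = wp * rec_p + wn * rec_n,
    f_measure = wp * f1(prec_p, rec_p) + wn * f1(prec_n, rec_n))
}
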