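# Front-quality metrics. A "front" here is a plain numeric matrix with one
# objective per column (all maximized); helpers accept anything coercible.

as_front <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  storage.mode(points) <- "double"
  points
}

# TRUE where row i is dominated by some other row (maximization)
dominated_rows <- function(P) {
  n <- nrow(P)
  dom <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(P[j, ] >= P[i, ]) && any(P[j, ] > P[i, ])) { dom[i] <- TRUE; break }
    }
  }
  dom
}

#' Nondominated subset of a point set
#'
#' Keeps the points not dominated by any other (maximization: dominated means
#' another point is >= in every objective and > in at least one). Exact
#' duplicates are collapsed to one copy afterwards unless `dedup = FALSE`.
#'
#' @param points matrix/data.frame of objective vectors, one row per point.
#' @param dedup drop exact duplicate rows after filtering (default TRUE).
#' @return Matrix of the nondominated points.
#' @export
nondominated <- function(points, dedup = TRUE) {
  P <- as_front(points)
  if (nrow(P) == 0L)
    stop_evohis("evohis_empty_front", "empty point set")
  out <- P[!dominated_rows(P), , drop = FALSE]
  if (dedup) out <- unique(out)
  out
}

#' Jointly min-max normalize an obtained front and a reference front
#'
#' Per-objective ranges are taken over the union of the two fronts and both
#' are rescaled to \[0, 1\]; an objective constant over the union maps to 0.
#' Using the union keeps `GD(Q, Q) = 0` after normalization.
#'
#' @param Q obtained front (matrix, one objective per column).
#' @param reference reference front with the same columns.
#' @return List with elements `Q` and `reference`, both rescaled.
#' @export
normalize_front <- function(Q, reference) {
  Q <- as_front(Q); R <- as_front(reference)
  U <- rbind(Q, R)
  lo <- apply(U, 2L, min); hi <- apply(U, 2L, max)
  span <- hi - lo
  scale1 <- function(P) {
    for (j in seq_len(ncol(P)))
      P[, j] <- if (span[j] == 0) 0 else (P[, j] - lo[j]) / span[j]
    P
  }
  list(Q = scale1(Q), reference = scale1(R))
}

#' Generational distance from an obtained front to a reference front
#'
#' `GD = (sum_i d_i^p)^(1/p) / |Q|` where `d_i` is the Euclidean distance from
#' the i-th member of `Q` to its nearest member of `Pstar`. Zero iff every
#' member of `Q` lies in `Pstar`.
#'
#' @param Q obtained front.
#' @param Pstar reference front.
#' @param p norm exponent (default 2).
#' @return Nonnegative scalar.
#' @export
generational_distance <- function(Q, Pstar, p = 2) {
  Q <- as_front(Q); P <- as_front(Pstar)
  if (nrow(Q) == 0L || nrow(P) == 0L)
    stop_evohis("evohis_empty_front", "both fronts must be nonempty")
  d <- vapply(seq_len(nrow(Q)), function(i) {
    min(sqrt(colSums((t(P) - Q[i, ])^2)))
  }, 0)
  sum(d^p)^(1 / p) / nrow(Q)
}

#' Spacing of a front (dispersion of nearest-neighbor distances)
#'
#' `d_i` is the Manhattan (absolute-difference-sum) distance from point i to
#' its nearest other member, and `S = sqrt(mean((d_i - dbar)^2))` — the
#' population standard deviation (1/|Q| normalization) of the `d_i`. Zero for
#' an evenly spaced front.
#'
#' @param Q front with at least two points.
#' @return Nonnegative scalar.
#' @export
spacing <- function(Q) {
  Q <- as_front(Q)
  if (nrow(Q) < 2L)
    stop_evohis("evohis_empty_front", "spacing needs at least 2 points")
  d <- vapply(seq_len(nrow(Q)), function(i) {
    min(colSums(abs(t(Q[-i, , drop = FALSE]) - Q[i, ])))
  }, 0)
  sqrt(mean((d - mean(d))^2))
}

#' Build a reference front from one or more evaluation archives
#'
#' Default mode takes the nondominated set of the union of all archived
#' objective vectors. Mode `"per_objective_max"` instead keeps, for each
#' objective, the points attaining that objective's maximum over the union
#' (an alternative reading of "maximum value for at least one objective").
#'
#' @param archives list of matrices/data.frames of objective vectors (e.g.
#'   the `PAC`, `SEY`, `SPY` columns of `evaluation_archive`s).
#' @param mode `"nondominated"` (default) or `"per_objective_max"`.
#' @return Matrix reference front.
#' @export
build_reference_front <- function(archives, mode = c("nondominated", "per_objective_max")) {
  mode <- match.arg(mode)
  if (!is.list(archives) || is.data.frame(archives)) archives <- list(archives)
  U <- do.call(rbind, lapply(archives, as_front))
  if (is.null(U) || nrow(U) == 0L)
    stop_evohis("evohis_empty_front", "no archived points")
  if (mode == "nondominated") return(nondominated(U))
  keep <- logical(nrow(U))
  for (j in seq_len(ncol(U))) keep[U[, j] == max(U[, j])] <- TRUE
  unique(U[keep, , drop = FALSE])
}
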