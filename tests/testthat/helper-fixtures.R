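# fixtures are built in code at test time; nothing is stored on disk

# tiny preprocessed dataset with a known linear signal
tiny_ds <- function(n = 60, d = 3, sep = 6, seed = 11, ...) {
  minmax_normalize(impute_missing(
    make_synthetic(synthetic_spec(n, d, class_separation = sep, seed = seed, ...))
  ))
}

write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

write_arff_fixture <- function(lines) {
  path <- tempfile(fileext = ".arff")
  writeLines(lines, path)
  path
}

# independent O(n^2) dominance oracle: plain enumeration, no shared helpers
brute_nondominated <- function(P) {
  n <- nrow(P)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      geq <- TRUE; gt <- FALSE
      for (m in seq_len(ncol(P))) {
        if (P[j, m] < P[i, m]) geq <- FALSE
        if (P[j, m] > P[i, m]) gt <- TRUE
      }
      if (geq && gt) { keep[i] <- FALSE; break }
    }
  }
  unique(P[keep, , drop = FALSE])
}

sorted_rows <- function(M) M[do.call(order, as.data.frame(M)), , drop = FALSE]

# small evolver budget for HIS runs inside tests (the package defaults stay
# at 20 agents x 50 iterations; tests shrink the budget, never thresholds)
small_budget <- function(n_agents = 5, n_iterations = 3)
  evolver_config(n_agents = n_agents, n_iterations = n_iterations)
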