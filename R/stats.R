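# Statistical validation harness: paired Wilcoxon signed-rank between two
# technique result vectors and a one-sample t-test over repeated runs, both
# two-sided at caller-chosen significance levels.

new_test_outcome <- function(p, alpha, statistic, ci = c(NA_real_, NA_real_),
                             method) {
  structure(list(p_value = p, reject_null = p < alpha, alpha = alpha,
                 statistic = statistic, ci_lower = ci[1L], ci_upper = ci[2L],
                 method = method),
            class = "evohis_test_outcome")
}

#' @export
print.evohis_test_outcome <- function(x, ...) {
  cat(sprintf("<%s> p = %.6g, h = %d (alpha = %g)\n",
              x$method, x$p_value, as.integer(x$reject_null), x$alpha))
  invisible(x)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Tests whether paired differences `x - y` are symmetric about zero.
#' Zero differences are dropped before ranking. The exact signed-rank null
#' distribution is used for n <= 25 untied differences; otherwise a normal
#' approximation with tie correction. `reject_null` (the "h" flag) is
#' `p_value < alpha`.
#'
#' @param x,y equal-length numeric vectors of paired results.
#' @param alpha two-sided significance level (default 0.05).
#' @return An `evohis_test_outcome`: `p_value`, `reject_null`, `alpha`,
#'   `statistic` (the positive-rank sum W+).
#' @export
wilcoxon_signed_rank <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y))
    stop_evohis("evohis_length_mismatch", "x (%d) and y (%d) lengths differ",
                length(x), length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)   # all pairs identical: no evidence against H0
    return(new_test_outcome(1, alpha, statistic = 0, method = "wilcoxon_signed_rank"))
  if (n < 5L)
    stop_evohis("evohis_too_few_pairs",
                "need >= 5 nonzero differences (got %d)", n)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    # exact: psignrank is the CDF of W+ under the null
    p <- min(1, 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n)))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  new_test_outcome(p, alpha, statistic = W, method = "wilcoxon_signed_rank")
}

#' Two-sided one-sample Student's t-test
#'
#' Tests H0: the population mean of `x` equals `m`, assuming normality with
#' unknown standard deviation. Also returns the two-sided `(1 - alpha)`
#' confidence interval for the mean.
#'
#' @param x numeric sample (length >= 2, nonzero variance).
#' @param m hypothesized mean.
#' @param alpha two-sided significance level (default 0.05).
#' @return An `evohis_test_outcome` with `ci_lower` / `ci_upper`.
#' @export
one_sample_t_test <- function(x, m, alpha = 0.05) {
  n <- length(x)
  if (n < 2L)
    stop_evohis("evohis_too_few_pairs", "need at least 2 observations")
  s <- sd(x)
  if (s == 0)
    stop_evohis("evohis_zero_variance", "sample has zero variance")
  se <- s / sqrt(n)
  tstat <- (mean(x) - m) / se
  p <- 2 * pt(-abs(tstat), df = n - 1)
  half <- qt(1 - alpha / 2, df = n - 1) * se
  new_test_outcome(p, alpha, statistic = tstat,
                   ci = c(mean(x) - half, mean(x) + half),
                   method = "one_sample_t")
}

#' Repeated seeded runs of a result-producing function
#'
#' Runs `runner(seed)` for seeds `base_seed, base_seed + 1, ...` and stacks
#' the returned (PAC, SEY, SPY) triples into a matrix, one row per run —
#' the sampling layer feeding the t-test harness.
#'
#' @param runner function taking a single integer seed and returning a
#'   numeric triple (named or not) of PAC, SEY, SPY.
#' @param n_runs number of runs (default 20).
#' @param base_seed first seed.
#' @return `n_runs` x 3 matrix with columns PAC, SEY, SPY.
#' @export
repeated_runs <- function(runner, n_runs = 20L, base_seed = 1L) {
  stopifnot(n_runs >= 1)
  out <- t(vapply(seq_len(n_runs), function(k) {
    v <- as.numeric(runner(base_seed + k - 1L))
    if (length(v) != 3L)
      stop_evohis("evohis_bad_runner", "runner must return a numeric triple")
    v
  }, numeric(3)))
  colnames(out) <- c("PAC", "SEY", "SPY")
  out
}
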