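---
title: "evohis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{evohis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`evohis` treats classifier tuning for disease diagnosis as a bounded
continuous optimization problem. For a binary dataset with `m1` positive and
`m2` negative instances, a classifier's quality is summarized by pooled
confusion counts over stratified k-fold cross-validation and the three
objectives

- prediction accuracy `PAC = (TP + TN) / N`,
- sensitivity `SEY = TP / (TP + FN) = TP / m1`,
- specificity `SPY = TN / (TN + FP) = TN / m2`.

Pooling counts across folds (rather than averaging per-fold rates) is what
makes the identities `TP + FN = m1` and `TN + FP = m2` hold exactly for the
whole dataset; it also implies the algebraic identity
`PAC = (m1·SEY + m2·SPY) / N`, which the test suite checks on random
confusion tables.

Rather than maintaining a Pareto front inside the search loop, the three
objectives are scalarized into `Z = w1·PAC + w2·SPY + w3·SEY` with convex
weights (defaults 0.95 / 0.025 / 0.025 — accuracy dominates, with a small
symmetric pull toward balanced error rates). `Z` is the single fitness every
evolver maximizes; the full objective triple of **every** evaluation is
archived so front-quality metrics can be computed after the fact.

## Classifiers and their evolvable parameters

All evolvable parameters live in `[0, 1]`.

| classifier | parameter | default | role |
|---|---|---|---|
| SVM | `cost` | 1 | soft-margin penalty `C`; 0 is lifted to `1e-6` so the solver stays defined |
| MLP | `learning_rate` | 0.3 | backprop step size `η` |
| MLP | `momentum` | 0.2 | fraction `α` of the previous weight update reapplied |

The defaults are the Weka SMO / MultilayerPerceptron defaults, which matters
because the evolver's initial population always contains the default vector:
under a shared fold seed, an evolved run's best `Z` is then mathematically
`>=` the baseline's.

The `[0, 1]` cost bound is unusual for an SVM (costs are often searched on a
log scale up to 10^3); it is kept deliberately because the whole search
design assumes a unit box. With a linear kernel on min–max-normalized
features the restriction is mild.

Both classifiers are implemented in compiled code inside the package because
no SVM/MLP implementation is available among the declared dependencies:

- **SVM**: dual coordinate descent on the hinge-loss dual with box constraint
  `0 <= alpha_i <= C`; the bias is absorbed as an augmented constant feature
  (linear) or an additive `+1` kernel term (RBF). Sweep order is drawn from
  R's RNG, so training is reproducible under a seed. Stopping: maximum
  projected-gradient violation `< 1e-3` or 1000 epochs.
- **MLP**: one hidden layer sized `round((d_in + 2) / 2)` (the mean of input
  and output layer sizes, two output units), logistic activations, squared
  error deltas, online updates `w <- w + η·δ·x + α·Δw_prev`, default 500
  epochs, weights initialized uniformly on `(-0.5, 0.5)` from R's RNG.
  Instances are visited in a fixed order; stochasticity enters only through
  initialization, which keeps fitness evaluation cheap and reproducible.

Nominal features are one-hot encoded using dataset-level level sets, so every
CV fold maps to identical columns.

## Preprocessing

- **Imputation**: per-feature mode for nominal features, per-feature mean for
  numeric ones. The numeric rule is our reading of "interval estimated data";
  the mean is the standard numeric analogue of the mode and keeps imputation
  a one-pass, leakage-simple operation. A fully missing feature is an error,
  not a guess.
- **Min–max normalization** to `[0, 1]` per numeric feature; a constant
  feature maps to 0 (the Weka convention — any constant is equally
  uninformative and this avoids 0/0). The map is idempotent.
- **Supervised resampling** replicates Weka's `Resample` filter: draw
  `round(n·size/100)` instances with replacement, choosing the class of each
  draw with probability interpolated between the empirical class distribution
  (bias 0) and uniform (bias 1), then an instance uniformly within the class.
  Defaults bias 0 / size 100%, matching the filter's defaults, because the
  original workflow only states that the filter was used. **Caveat**: as in
  that workflow, resampling is applied to the whole dataset *before*
  cross-validation, so resampled figures carry an optimistic bias (duplicated
  instances can appear in both training and test folds). This is reproduced,
  not corrected; compare resampled cells only with other resampled cells.

## The evolvers

All three maximize over the box, clamp positions to bounds after every move
(the simplest feasibility repair), raise a classed error on non-finite
fitness, and are bit-reproducible per seed. Best-ever solutions are tracked
outside the swarm state (GSA and FA have no native memory), which is what
makes `fitness_history` nondecreasing.

- **PSO**: `v <- w·v + c1·r1·(pBest − x) + c2·r2·(gBest − x)` with
  per-dimension uniform randoms; `w = 0.729`, `c1 = c2 = 1.49445` (standard
  constriction-equivalent constants).
- **GSA**: masses `q_i = (fit_i − worst) / (best − worst)` normalized to sum
  to 1, with `best = max`, `worst = min` (the printed minimization form is
  flipped because `Z` is maximized). Acceleration of agent `i` sums
  `rand_j·G(t)·M_j·(x_j − x_i) / (R_ij + ε)` over the `kbest` heaviest
  agents; velocity is `rand_i·v + a` with a per-agent scalar `rand_i`, as
  printed. `G(t) = G0·exp(−20·t/T)`; `kbest` decays linearly from the swarm
  size to 1. **`G0 = 1`, not the customary 100**: the customary value was
  calibrated for benchmark domains hundreds of units wide, and on a unit
  hyperparameter box it saturates every agent against the bounds for the
  first quarter of the run. On plateaued fitness (anything derived from
  discrete CV counts, or a grid-discretized test function) the swarm then
  freezes wherever it collapsed: measured on a 101-point discretized 1-D
  fitness, GSA recovers the exhaustive-search argmax within one grid step in
  12/20 seeds at `G0 = 100` versus 20/20 at `G0 <= 10`. `G0` remains a
  config knob for anyone wanting the historical value.
- **FA**: brightness = fitness; firefly `i` moves toward every strictly
  brighter `j` by `β0·exp(−γ·r^m)·(x_j − x_i) + α·(rand − 0.5)` with `r`
  Euclidean, `β0 = γ = 1`, `m = 2`, `α = 0.2`. Sweeps are **sequential**:
  updated positions (and re-evaluated brightnesses) are visible within the
  same sweep, following the classical pseudocode; a firefly with no brighter
  peer takes only the random step. This costs up to `n²` evaluations per
  sweep — the price of the algorithm's design, which is why FA archives are
  much larger than PSO/GSA archives at the same budget.

## Front metrics

Fronts are matrices with one objective per column, all maximized.

- `nondominated()` keeps points not dominated by any other and collapses
  exact duplicates (toggleable); it is validated against brute-force
  enumeration on random 3-D fronts.
- `generational_distance(Q, P*) = (Σ d_i^p)^(1/p) / |Q|` with Euclidean
  nearest-neighbor `d_i` — note the division by `|Q|` *outside* the root, as
  printed in the source convention.
- `spacing(Q)` uses Manhattan nearest-neighbor distances and the population
  (1/|Q|) standard deviation. Schott's original uses `1/(|Q|−1)`; the
  printed `1/|Q|` form is implemented.
- Normalization for GD/SP uses per-objective min–max over the **union** of
  `Q` and the reference front; normalizing `Q` alone (a literal reading of
  the source) would break the property `GD = 0` when `Q ⊆ P*`.
- Two reference-front modes: the nondominated set of all archived points
  (default), or the points attaining each objective's maximum. They differ:
  for `{(1,0), (0,1), (0.4,0.4)}` the default keeps all three (nothing
  dominates `(0.4,0.4)`), the per-objective-max mode keeps the two extremes.
  Neither is endorsed; both are exposed.

## Statistical harness

`wilcoxon_signed_rank()` drops zero differences, uses the exact signed-rank
null distribution for `n <= 25` untied differences (the regimes that occur
with 11 datasets or 20 runs), and a tie-corrected normal approximation
otherwise; `one_sample_t_test()` is the closed-form two-sided t with a
`(1 − alpha)` CI. Both are written from first principles and tested to
`1e-6` against the independent reference implementations in the `stats`
package. Note the signed-rank p-value is invariant under *affine* maps of
both samples but not under general monotone transforms (ranks of difference
magnitudes are not preserved); only affine invariance is claimed or tested.
No multiple-testing correction is applied across harness comparisons,
mirroring the source workflow.

## Synthetic data: what a green test establishes

`make_synthetic()` draws two Gaussian class-conditional clouds with identity
covariance whose means are `class_separation` within-class standard
deviations apart along a random unit direction, binomial class assignment,
optional Bernoulli label flips and cell masking. This reproduces the *shape*
of the UCI-style clinical tables (size, dimensionality, imbalance,
missingness) and gives known ground truth: separation 6 must yield CV
accuracy ≥ 0.95 for any sane linear classifier, separation 0 must pin every
classifier near chance.

It deliberately does **not** emulate: correlated or heteroscedastic
features, mixed nominal/numeric clinical codings, non-Gaussian class shapes,
or missingness that depends on the data (masking is MCAR). A green test
therefore certifies the machinery — preprocessing, CV bookkeeping, evolver
convergence, determinism — not clinical performance on any real dataset.

## Numerical conventions and degenerate inputs

- Seeds: one master seed fans out by fixed offsets to fold shuffling,
  resampling, training and the evolver; all sub-seeds stay below 2^31.
- Stratified folds: within-class shuffle + round-robin deal, so each fold's
  class fraction is within one instance of the global fraction; fold
  assignment depends only on `(n, labels, shuffle_seed)`.
- Ties in `select_best`: higher PAC, then classifier order (svm, mlp), then
  evolver order (none, pso, gsa, fa), then unresampled first.
- Degenerate cases: all-equal fitness gives GSA equal masses (no force) and
  FA random walks; a search interval with `lower == upper` is a fixed point;
  all-zero Wilcoxon differences return `p = 1` rather than erroring; a
  zero-variance t-test sample errors (its statistic is undefined); 0/0
  per-class secondary metrics contribute 0 with a warning.
- MLP epoch budget (500) follows the Weka default since no stopping rule is
  given; tests and the acceptance script cut epochs and evolver budgets for
  runtime, never thresholds.

## Known limitations

- The resample-before-CV optimistic bias described above.
- CV-optimized figures are reported directly (no held-out re-evaluation), as
  in the source workflow; treat absolute numbers as model-selection scores.
- Only binary classification; no feature selection; SVM evolves cost only
  (kernel width is fixed); MLP evolves `η`/`α` only (topology is ruled).
- FA's `O(n²)` evaluation cost makes it the slowest hybrid at equal budgets.
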