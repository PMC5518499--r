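#' Bounded search-space parameter
#'
#' @param name parameter name.
#' @param lower,upper bounds, `lower <= upper`.
#' @return An object of class `evohis_parameter_spec`.
#' @export
parameter_spec <- function(name, lower = 0, upper = 1) {
  stopifnot(is.character(name), length(name) == 1L, lower <= upper)
  structure(list(name = name, lower = lower, upper = upper),
            class = "evohis_parameter_spec")
}

space_bounds <- function(space) {
  stopifnot(length(space) >= 1L)
  list(names = vapply(space, `[[`, "", "name"),
       lower = vapply(space, `[[`, 0, "lower"),
       upper = vapply(space, `[[`, 0, "upper"))
}

#' Componentwise clamp of a position to the search box
#'
#' @param position numeric vector.
#' @param space list of [parameter_spec()].
#' @return Clamped position.
#' @export
clip_to_bounds <- function(position, space) {
  b <- space_bounds(space)
  pmin(pmax(position, b$lower), b$upper)
}

#' Evolver configuration
#'
#' Defaults follow the run budget used throughout: 20 agents evolved for 50
#' iterations. Algorithm blocks:
#' \describe{
#'   \item{pso}{inertia `w` = 0.729 and learning factors `c1` = `c2` = 1.49445
#'     (standard constriction-equivalent constants).}
#'   \item{gsa}{gravitational constant schedule `G(t) = G0 exp(-decay_rate *
#'     t / T)` with `decay_rate` = 20 (the usual GSA setting) and `G0` = 1.
#'     `G0` sets the force scale relative to the search domain; the customary
#'     `G0` = 100 was calibrated for benchmark boxes hundreds of units wide
#'     and saturates a unit hyperparameter box (agents slam into the bounds
#'     for the first quarter of the run and cannot refine on plateaued
#'     fitness), so the default here is scaled to the box diagonal.
#'     `epsilon` is the small distance offset; `kbest` shrinks linearly from
#'     the swarm size to `kbest_final` (default 1).}
#'   \item{fa}{attractiveness `beta0` = 1 with decay `beta0 * exp(-gamma *
#'     r^exponent)` (`gamma` = 1, `exponent` = 2) and random-step scale
#'     `alpha` = 0.2.}
#' }
#'
#' @param n_agents swarm size.
#' @param n_iterations iteration budget.
#' @param seed RNG seed; identical seeds give bit-identical runs.
#' @param pso,gsa,fa named lists overriding the per-algorithm defaults.
#' @param init_positions optional matrix of positions injected into the
#'   initial swarm (rows, recycled into the first agents).
#' @return An object of class `evohis_evolver_config`.
#' @export
evolver_config <- function(n_agents = 20L, n_iterations = 50L, seed = 1L,
                           pso = list(), gsa = list(), fa = list(),
                           init_positions = NULL) {
  stopifnot(n_agents >= 1, n_iterations >= 1)
  structure(list(
    n_agents = as.integer(n_agents), n_iterations = as.integer(n_iterations),
    seed = as.integer(seed),
    pso = utils::modifyList(list(w = 0.729, c1 = 1.49445, c2 = 1.49445), pso),
    gsa = utils::modifyList(list(G0 = 1, decay_rate = 20, epsilon = 1e-10,
                                 kbest_final = 1L), gsa),
    fa = utils::modifyList(list(beta0 = 1, gamma = 1, alpha = 0.2, exponent = 2), fa),
    init_positions = init_positions
  ), class = "evohis_evolver_config")
}

# --- shared swarm infrastructure ------------------------------------------

# archive accumulator: one row per fitness evaluation
new_archiver <- function(param_names) {
  e <- new.env(parent = emptyenv())
  e$rows <- list(); e$param_names <- param_names
  e
}

archive_eval <- function(arch, iteration, agent, position, fitness) {
  obj <- attr(fitness, "objectives")
  row <- c(iteration = iteration, agent = agent,
           stats::setNames(as.numeric(position), arch$param_names),
           Z = as.numeric(fitness))
  if (!is.null(obj)) row <- c(row, obj)
  arch$rows[[length(arch$rows) + 1L]] <- row
}

archive_df <- function(arch) {
  as.data.frame(do.call(rbind, arch$rows))
}

# evaluate, validate and archive; returns scalar fitness
make_evaluator <- function(fitness, arch) {
  function(position, iteration, agent) {
    f <- fitness(position)
    if (!is.finite(f)) {
      cond <- structure(
        class = c("evohis_eval_error", "evohis_error", "error", "condition"),
        list(message = sprintf("non-finite fitness at position (%s)",
                               paste(signif(position, 6), collapse = ", ")),
             call = sys.call(-1), position = position))
      stop(cond)
    }
    archive_eval(arch, iteration, agent, position, f)
    as.numeric(f)
  }
}

init_swarm <- function(cfg, b) {
  d <- length(b$lower)
  X <- matrix(runif(cfg$n_agents * d, rep(b$lower, each = cfg$n_agents),
                    rep(b$upper, each = cfg$n_agents)),
              cfg$n_agents, d)
  if (!is.null(cfg$init_positions)) {
    P <- matrix(cfg$init_positions, ncol = d)
    k <- min(nrow(P), cfg$n_agents)
    for (i in seq_len(k))
      X[i, ] <- pmin(pmax(P[i, ], b$lower), b$upper)
  }
  X
}

finish_result <- function(best_x, best_f, history, arch, b) {
  structure(list(best_position = stats::setNames(best_x, b$names),
                 best_fitness = best_f, fitness_history = history,
                 evaluation_archive = archive_df(arch)),
            class = "evohis_optim_result")
}

#' @export
print.evohis_optim_result <- function(x, ...) {
  cat(sprintf("<optim result> best Z = %.6f at (%s); %d evaluations\n",
              x$best_fitness,
              paste(sprintf("%s=%.4f", names(x$best_position), x$best_position),
                    collapse = ", "),
              nrow(x$evaluation_archive)))
  invisible(x)
}

# --- particle swarm optimization ------------------------------------------

#' Particle swarm optimization over a bounded box (maximization)
#'
#' Velocity update `v <- w*v + c1*rand*(pBest - x) + c2*rand*(gBest - x)`
#' (per-dimension uniform randoms), position update `x <- x + v` clipped to
#' the bounds. pBest/gBest track the best fitness seen (maximization).
#'
#' @param fitness function mapping a position vector to a finite scalar to be
#'   maximized; it may attach an `objectives` attribute (named numeric) which
#'   is stored in the evaluation archive.
#' @param space list of [parameter_spec()].
#' @param cfg an [evolver_config()].
#' @return An `evohis_optim_result`: `best_position`, `best_fitness`,
#'   nondecreasing `fitness_history` (initial evaluation + one entry per
#'   iteration), and `evaluation_archive` (one row per evaluation).
#' @export
pso_optimize <- function(fitness, space, cfg = evolver_config()) {
  b <- space_bounds(space); d <- length(b$lower)
  arch <- new_archiver(b$names)
  ev <- make_evaluator(fitness, arch)
  p <- cfg$pso
  withr::with_seed(cfg$seed, {
    X <- init_swarm(cfg, b)
    V <- matrix(0, cfg$n_agents, d)
    fit <- vapply(seq_len(cfg$n_agents), function(i) ev(X[i, ], 0L, i), 0)
    pbest <- X; pbest_fit <- fit
    g <- which.max(fit); gbest <- X[g, ]; gbest_fit <- fit[g]
    history <- gbest_fit
    for (t in seq_len(cfg$n_iterations)) {
      for (i in seq_len(cfg$n_agents)) {
        V[i, ] <- p$w * V[i, ] +
          p$c1 * runif(d) * (pbest[i, ] - X[i, ]) +
          p$c2 * runif(d) * (gbest - X[i, ])
        X[i, ] <- pmin(pmax(X[i, ] + V[i, ], b$lower), b$upper)
        f <- ev(X[i, ], t, i)
        if (f > pbest_fit[i]) { pbest[i, ] <- X[i, ]; pbest_fit[i] <- f }
        if (f > gbest_fit) { gbest <- X[i, ]; gbest_fit <- f }
      }
      history <- c(history, gbest_fit)
    }
    finish_result(gbest, gbest_fit, history, arch, b)
  })
}

# --- gravitational search algorithm ---------------------------------------

#' Gravitational search over a bounded box (maximization)
#'
#' Agents are masses attracting one another. Each iteration, fitnesses are
#' normalized to masses (`q_i = (fit_i - worst) / (best - worst)`, best = max
#' and worst = min under maximization, masses summing to 1), the `kbest`
#' heaviest agents exert force `rand_j * G(t) * M_j * (x_j - x_i) /
#' (R_ij + epsilon)` on every agent, velocities update as `rand_i * v + a`
#' and positions move and are clipped. `G(t)` decays exponentially and
#' `kbest` shrinks linearly to `kbest_final`. GSA itself is memoryless, so
#' the best-ever solution is tracked externally.
#'
#' @inheritParams pso_optimize
#' @return An `evohis_optim_result` (see [pso_optimize()]).
#' @export
gsa_optimize <- function(fitness, space, cfg = evolver_config()) {
  b <- space_bounds(space); d <- length(b$lower)
  n <- cfg$n_agents; T_ <- cfg$n_iterations
  arch <- new_archiver(b$names)
  ev <- make_evaluator(fitness, arch)
  g <- cfg$gsa
  withr::with_seed(cfg$seed, {
    X <- init_swarm(cfg, b)
    V <- matrix(0, n, d)
    fit <- vapply(seq_len(n), function(i) ev(X[i, ], 0L, i), 0)
    best_i <- which.max(fit); best_x <- X[best_i, ]; best_f <- fit[best_i]
    history <- best_f
    for (t in seq_len(T_)) {
      best_t <- max(fit); worst_t <- min(fit)
      q <- if (best_t == worst_t) rep(1, n) else (fit - worst_t) / (best_t - worst_t)
      M <- if (sum(q) == 0) rep(1 / n, n) else q / sum(q)
      Gt <- g$G0 * exp(-g$decay_rate * t / T_)
      kbest <- as.integer(round(n + (g$kbest_final - n) * (t - 1) / max(1L, T_ - 1L)))
      kidx <- order(M, decreasing = TRUE)[seq_len(max(1L, kbest))]
      A <- matrix(0, n, d)
      for (i in seq_len(n)) {
        for (j in kidx) {
          if (j == i) next
          R <- sqrt(sum((X[i, ] - X[j, ])^2))
          # force divided by M_i: acceleration depends on the source mass only
          A[i, ] <- A[i, ] + runif(1) * Gt * M[j] * (X[j, ] - X[i, ]) / (R + g$epsilon)
        }
      }
      for (i in seq_len(n)) {
        V[i, ] <- runif(1) * V[i, ] + A[i, ]
        X[i, ] <- pmin(pmax(X[i, ] + V[i, ], b$lower), b$upper)
      }
      fit <- vapply(seq_len(n), function(i) ev(X[i, ], t, i), 0)
      if (max(fit) > best_f) {
        best_i <- which.max(fit); best_x <- X[best_i, ]; best_f <- fit[best_i]
      }
      history <- c(history, best_f)
    }
    finish_result(best_x, best_f, history, arch, b)
  })
}

# --- firefly algorithm -----------------------------------------------------

#' Firefly algorithm over a bounded box (maximization)
#'
#' Brightness equals fitness. In each sweep, firefly `i` moves toward every
#' strictly brighter firefly `j` by `beta0 * exp(-gamma * r^m) * (x_j - x_i)
#' + alpha * (rand - 0.5)` with `r` the Euclidean distance; moves are
#' sequential, so updated positions are visible within the sweep and each
#' move is re-evaluated. A firefly with no brighter peer takes only the
#' random step. Best-ever is tracked externally.
#'
#' @inheritParams pso_optimize
#' @return An `evohis_optim_result` (see [pso_optimize()]).
#' @export
fa_optimize <- function(fitness, space, cfg = evolver_config()) {
  b <- space_bounds(space); d <- length(b$lower)
  n <- cfg$n_agents
  arch <- new_archiver(b$names)
  ev <- make_evaluator(fitness, arch)
  fp <- cfg$fa
  withr::with_seed(cfg$seed, {
    X <- init_swarm(cfg, b)
    I <- vapply(seq_len(n), function(i) ev(X[i, ], 0L, i), 0)
    best_i <- which.max(I); best_x <- X[best_i, ]; best_f <- I[best_i]
    history <- best_f
    for (t in seq_len(cfg$n_iterations)) {
      for (i in seq_len(n)) {
        moved <- FALSE
        for (j in seq_len(n)) {
          if (j == i || I[j] <= I[i]) next
          r <- sqrt(sum((X[i, ] - X[j, ])^2))
          beta <- fp$beta0 * exp(-fp$gamma * r^fp$exponent)
          X[i, ] <- pmin(pmax(X[i, ] + beta * (X[j, ] - X[i, ]) +
                                fp$alpha * (runif(d) - 0.5),
                              b$lower), b$upper)
          I[i] <- ev(X[i, ], t, i)
          moved <- TRUE
          if (I[i] > best_f) { best_x <- X[i, ]; best_f <- I[i] }
        }
        if (!moved) {
          X[i, ] <- pmin(pmax(X[i, ] + fp$alpha * (runif(d) - 0.5),
                              b$lower), b$upper)
          I[i] <- ev(X[i, ], t, i)
          if (I[i] > best_f) { best_x <- X[i, ]; best_f <- I[i] }
        }
      }
      history <- c(history, best_f)
    }
    finish_result(best_x, best_f, history, arch, b)
  })
}
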