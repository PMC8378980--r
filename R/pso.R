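# Improved particle swarm optimizer (IPSO): a global-best PSO whose velocity
# update is damped by a shrinkage (constriction) factor that decreases
# linearly over iterations, plus a standard inertia-weight PSO baseline.

#' Particle swarm optimizer configuration
#'
#' Bundles the hyperparameters of the improved particle swarm optimizer. The
#' shrinkage factor decreases linearly from `p_max` at iteration 0 to `p_min`
#' at iteration `n_max` (see [shrinkage_factor()]); it multiplies the whole
#' velocity update, inertia term included, so setting `p_max = p_min = 1`
#' recovers the plain inertia-weight PSO.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param n_max Maximum number of iterations (>= 1).
#' @param p_max,p_min Upper and lower bounds of the shrinkage factor,
#'   `p_max >= p_min > 0`.
#' @param inertia_weight Nonnegative coefficient on the previous velocity.
#' @param c1,c2 Nonnegative cognitive (personal-best) and social (global-best)
#'   acceleration coefficients; `c1 + c2` must be positive.
#' @param v_max Per-dimension velocity clamp. `NULL` (default) resolves, once
#'   bounds are known, to 20% of each dimension's range.
#' @param seed Integer seed; every run of the optimizer is a pure function of
#'   the configuration, bounds, objective and this seed.
#' @param stall_tolerance,stall_window Optional early stopping: stop when the
#'   global-best fitness has improved by less than `stall_tolerance` over
#'   `stall_window` consecutive iterations. `stall_window = 0` (default)
#'   disables early stopping.
#' @return An object of class `pso_config`.
#' @export
#' @examples
#' cfg <- pso_config(swarm_size = 10, n_max = 50, seed = 42)
#' cfg$p_max
pso_config <- function(swarm_size = 30L, n_max = 100L,
                       p_max = 0.9, p_min = 0.4,
                       inertia_weight = 1.0, c1 = 2.0, c2 = 2.0,
                       v_max = NULL, seed = 1L,
                       stall_tolerance = 0, stall_window = 0L) {
  if (!is_scalar_number(swarm_size) || swarm_size < 2) {
    abort_param("`swarm_size` must be an integer >= 2")
  }
  if (!is_scalar_number(n_max) || n_max < 1) {
    abort_param("`n_max` must be an integer >= 1")
  }
  if (!is_scalar_number(p_max) || !is_scalar_number(p_min) ||
      p_min <= 0 || p_max < p_min) {
    abort_param("shrinkage bounds must satisfy p_max >= p_min > 0")
  }
  if (!is_scalar_number(inertia_weight) || inertia_weight < 0) {
    abort_param("`inertia_weight` must be nonnegative")
  }
  if (!is_scalar_number(c1) || !is_scalar_number(c2) || c1 < 0 || c2 < 0 ||
      c1 + c2 <= 0) {
    abort_param("`c1` and `c2` must be nonnegative with c1 + c2 > 0")
  }
  if (!is.null(v_max) && (!is.numeric(v_max) || any(v_max <= 0))) {
    abort_param("`v_max` must be positive")
  }
  if (!is_scalar_number(stall_tolerance) || stall_tolerance < 0) {
    abort_param("`stall_tolerance` must be nonnegative")
  }
  if (!is_scalar_number(stall_window) || stall_window < 0) {
    abort_param("`stall_window` must be a nonnegative integer")
  }
  structure(
    list(
      swarm_size = as.integer(swarm_size), n_max = as.integer(n_max),
      p_max = p_max, p_min = p_min,
      inertia_weight = inertia_weight, c1 = c1, c2 = c2,
      v_max = v_max, seed = as.integer(seed),
      stall_tolerance = stall_tolerance, stall_window = as.integer(stall_window)
    ),
    class = "pso_config"
  )
}

#' Search bounds for the optimizer
#'
#' @param lower,upper Numeric vectors of per-dimension limits with
#'   `lower < upper` in every dimension.
#' @return An object of class `search_bounds`.
#' @export
search_bounds <- function(lower, upper) {
  if (length(lower) != length(upper) || length(lower) < 1L) {
    abort_param("`lower` and `upper` must be equal-length, nonempty vectors")
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || any(lower >= upper)) {
    abort_param("bounds must be finite with lower < upper in every dimension")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 dim = length(lower)),
            class = "search_bounds")
}

resolve_v_max <- function(config, bounds) {
  if (is.null(config$v_max)) {
    0.2 * (bounds$upper - bounds$lower)
  } else {
    rep_len(config$v_max, bounds$dim)
  }
}

#' Linearly decreasing shrinkage factor
#'
#' The shrinkage (constriction) factor at iteration `n`:
#' `p_max - (p_max - p_min) * n / n_max`. It equals `p_max` at `n = 0`,
#' `p_min` at `n = n_max`, and is affine in `n` in between.
#'
#' @param n Current iteration number, `0 <= n <= n_max`.
#' @param config A [pso_config()].
#' @return The shrinkage factor, a number in `[p_min, p_max]`.
#' @export
#' @examples
#' cfg <- pso_config(n_max = 100, p_max = 0.9, p_min = 0.4)
#' shrinkage_factor(0, cfg)    # 0.9
#' shrinkage_factor(50, cfg)   # 0.65
#' shrinkage_factor(100, cfg)  # 0.4
shrinkage_factor <- function(n, config) {
  if (!is.numeric(n) || any(n < 0) || any(n > config$n_max)) {
    abort_domain(sprintf("iteration `n` must lie in [0, %d]", config$n_max))
  }
  config$p_max - (config$p_max - config$p_min) * n / config$n_max
}

eval_objective <- function(objective, position) {
  f <- objective(position)
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || is.nan(f) || f == Inf) {
    abort_eval(sprintf(
      "objective returned a non-numeric, NA/NaN or +Inf value at position (%s)",
      paste(signif(position, 6), collapse = ", ")
    ))
  }
  # -Inf is allowed: it marks an infeasible candidate under maximization.
  as.numeric(f)
}

#' Initialize a particle swarm
#'
#' Draws `swarm_size` particle positions uniformly within the bounds and
#' velocities uniformly in `[-v_max, v_max]`, evaluates the objective at every
#' position, and sets the personal bests and the global best. Seeded: the same
#' configuration yields the same swarm. An objective value of `-Inf` is
#' treated as "infeasible candidate" (this is how discrete decodings signal
#' invalid threshold sets), not as an evaluation failure.
#'
#' @param config A [pso_config()].
#' @param bounds A [search_bounds()].
#' @param objective Function mapping a numeric vector to a single number, to
#'   be maximized.
#' @param seed Seed for the draw; defaults to `config$seed`. `NULL` uses the
#'   current RNG state (used internally by [pso_optimize()]).
#' @return A `swarm_state` list: `positions` and `velocities` (swarm-by-dim
#'   matrices), `pbest_positions`, `pbest_fitness`, `gbest_position`,
#'   `gbest_fitness`, `iteration`.
#' @export
initialize_swarm <- function(config, bounds, objective, seed = config$seed) {
  draw <- function() {
    d <- bounds$dim
    s <- config$swarm_size
    v_max <- resolve_v_max(config, bounds)
    positions <- matrix(runif(s * d, rep(bounds$lower, each = s),
                              rep(bounds$upper, each = s)), s, d)
    velocities <- matrix(runif(s * d, rep(-v_max, each = s),
                               rep(v_max, each = s)), s, d)
    fitness <- vapply(seq_len(s),
                      function(i) eval_objective(objective, positions[i, ]),
                      numeric(1))
    best <- which.max(fitness)
    structure(
      list(positions = positions, velocities = velocities,
           pbest_positions = positions, pbest_fitness = fitness,
           gbest_position = positions[best, ], gbest_fitness = fitness[best],
           iteration = 0L),
      class = "swarm_state"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Velocity update for one particle
#'
#' Computes the new velocity
#' `factor * (w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x))`,
#' then clamps each component to `[-v_max, v_max]`. The random draws `r1`,
#' `r2` are per-dimension vectors in `[0, 1]`, injectable for testing.
#'
#' @param particle List with numeric vectors `position`, `velocity`,
#'   `pbest_position` of one common dimension.
#' @param gbest_position Global-best position vector.
#' @param factor Shrinkage factor in `[p_min, p_max]` (or 1 for standard PSO).
#' @param config A [pso_config()].
#' @param r1,r2 Uniform random vectors in `[0, 1]`, one entry per dimension.
#' @param v_max Per-dimension clamp (vector); defaults to `config$v_max`.
#' @return The clamped new velocity vector.
#' @export
velocity_update <- function(particle, gbest_position, factor, config,
                            r1, r2, v_max = config$v_max) {
  d <- length(particle$position)
  lens <- c(length(particle$velocity), length(particle$pbest_position),
            length(gbest_position), length(r1), length(r2))
  if (any(lens != d)) {
    abort_contract("particle vectors, gbest and random draws must share one dimension")
  }
  v <- factor * (config$inertia_weight * particle$velocity +
                   config$c1 * r1 * (particle$pbest_position - particle$position) +
                   config$c2 * r2 * (gbest_position - particle$position))
  clamp(v, -rep_len(v_max, d), rep_len(v_max, d))
}

#' Position update for one particle
#'
#' Moves the particle by its new velocity and clamps the result into the
#' bounds; wherever a component was clamped the residual velocity is zeroed so
#' particles do not press against the walls.
#'
#' @param particle List with a numeric `position`.
#' @param new_velocity Velocity vector from [velocity_update()].
#' @param bounds A [search_bounds()].
#' @return List with the clamped `position` and the residual `velocity`.
#' @export
position_update <- function(particle, new_velocity, bounds) {
  if (length(new_velocity) != length(particle$position)) {
    abort_contract("velocity and position must share one dimension")
  }
  raw <- particle$position + new_velocity
  pos <- clamp(raw, bounds$lower, bounds$upper)
  vel <- ifelse(pos == raw, new_velocity, 0)
  list(position = pos, velocity = vel)
}

#' Advance the swarm by one iteration
#'
#' Applies [velocity_update()] and [position_update()] to every particle with
#' the shrinkage factor of the current iteration, re-evaluates the objective,
#' refreshes personal and global bests and increments the iteration counter.
#' The global-best fitness never decreases.
#'
#' @param state A `swarm_state` from [initialize_swarm()] or a previous step.
#' @param config A [pso_config()].
#' @param bounds A [search_bounds()].
#' @param objective Objective function (maximized).
#' @param factor Shrinkage factor override; by default
#'   `shrinkage_factor(state$iteration, config)`. [pso_optimize_standard()]
#'   passes 1.
#' @return The successor `swarm_state`.
#' @export
swarm_step <- function(state, config, bounds, objective,
                       factor = shrinkage_factor(state$iteration, config)) {
  if (state$iteration >= config$n_max) {
    abort_domain("swarm has already reached `n_max` iterations")
  }
  s <- config$swarm_size
  d <- bounds$dim
  v_max <- resolve_v_max(config, bounds)
  r1 <- matrix(runif(s * d), s, d)
  r2 <- matrix(runif(s * d), s, d)
  for (i in seq_len(s)) {
    p <- list(position = state$positions[i, ],
              velocity = state$velocities[i, ],
              pbest_position = state$pbest_positions[i, ])
    v <- velocity_update(p, state$gbest_position, factor, config,
                         r1[i, ], r2[i, ], v_max = v_max)
    moved <- position_update(p, v, bounds)
    state$positions[i, ] <- moved$position
    state$velocities[i, ] <- moved$velocity
    f <- eval_objective(objective, moved$position)
    if (f > state$pbest_fitness[i]) {
      state$pbest_fitness[i] <- f
      state$pbest_positions[i, ] <- moved$position
    }
  }
  best <- which.max(state$pbest_fitness)
  if (state$pbest_fitness[best] > state$gbest_fitness) {
    state$gbest_fitness <- state$pbest_fitness[best]
    state$gbest_position <- state$pbest_positions[best, ]
  }
  state$iteration <- state$iteration + 1L
  state
}

run_pso <- function(objective, bounds, config, factor_fn, method) {
  withr::with_seed(config$seed, {
    state <- initialize_swarm(config, bounds, objective, seed = NULL)
    trace <- numeric(config$n_max)
    iterations <- 0L
    converged_early <- FALSE
    for (n in seq_len(config$n_max)) {
      state <- swarm_step(state, config, bounds, objective,
                          factor = factor_fn(state$iteration, config))
      iterations <- n
      trace[n] <- state$gbest_fitness
      w <- config$stall_window
      if (w > 0L && n > w) {
        improvement <- trace[n] - trace[n - w]
        if (is.finite(improvement) && improvement < config$stall_tolerance) {
          converged_early <- TRUE
          break
        }
      }
    }
    structure(
      list(best_position = state$gbest_position,
           best_fitness = state$gbest_fitness,
           fitness_trace = trace[seq_len(iterations)],
           iterations_run = iterations,
           converged_early = converged_early,
           method = method, config = config),
      class = "pso_result"
    )
  })
}

#' Maximize an objective with the improved PSO
#'
#' Runs the shrinkage-factor PSO: the swarm is initialized from
#' `config$seed`, then stepped for up to `n_max` iterations with the factor
#' of [shrinkage_factor()] applied at each iteration. Minimization problems
#' are handled by negating the objective.
#'
#' @inheritParams initialize_swarm
#' @return A `pso_result`: `best_position`, `best_fitness`, `fitness_trace`
#'   (global best after each iteration, non-decreasing), `iterations_run`,
#'   `converged_early`, `method`, and the `config` used.
#' @seealso [pso_optimize_standard()] for the fixed-factor baseline,
#'   [tidy.pso_result()] and [autoplot.pso_result()] for inspection.
#' @export
#' @examples
#' res <- pso_optimize(function(x) -(x - 128)^2,
#'                     search_bounds(0, 255),
#'                     pso_config(swarm_size = 20, seed = 1))
#' res$best_position
pso_optimize <- function(objective, bounds, config = pso_config()) {
  run_pso(objective, bounds, config, shrinkage_factor, "ipso")
}

#' Maximize an objective with standard inertia-weight PSO
#'
#' Identical to [pso_optimize()] but with the shrinkage factor fixed to 1,
#' i.e. the plain global-best PSO with an inertia weight. Used as the
#' comparison baseline for the improved optimizer.
#'
#' @inheritParams pso_optimize
#' @return A `pso_result` with `method = "standard"`.
#' @export
pso_optimize_standard <- function(objective, bounds, config = pso_config()) {
  run_pso(objective, bounds, config, function(n, cfg) 1, "standard")
}

#' Run the improved and standard PSO side by side
#'
#' Convenience harness for comparing the two optimizers on one objective with
#' one configuration and seed.
#'
#' @inheritParams pso_optimize
#' @return A tibble with columns `method`, `iteration`, `gbest_fitness`.
#' @export
compare_pso <- function(objective, bounds, config = pso_config()) {
  res <- list(ipso = pso_optimize(objective, bounds, config),
              standard = pso_optimize_standard(objective, bounds, config))
  purrr::map_dfr(res, tidy, .id = NULL)
}

#' @rdname pso_optimize
#' @param x A `pso_result`.
#' @param ... Unused.
#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf(
    "<pso_result: %s>\n  best fitness %.6g at (%s)\n  %d iteration(s)%s\n",
    x$method, x$best_fitness,
    paste(signif(x$best_position, 6), collapse = ", "),
    x$iterations_run,
    if (x$converged_early) ", stalled early" else ""
  ))
  invisible(x)
}

#' Tidy the iteration trace of a PSO run
#'
#' @param x A `pso_result`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `iteration`, `gbest_fitness`.
#' @export
tidy.pso_result <- function(x, ...) {
  tibble(method = x$method,
         iteration = seq_len(x$iterations_run),
         gbest_fitness = x$fitness_trace)
}

#' One-row summary of a PSO run
#'
#' @param x A `pso_result`.
#' @param ... Unused.
#' @return A one-row tibble with the best fitness, iteration count and
#'   early-convergence flag.
#' @export
glance.pso_result <- function(x, ...) {
  tibble(method = x$method, best_fitness = x$best_fitness,
         iterations_run = x$iterations_run,
         converged_early = x$converged_early)
}

#' Plot the global-best fitness trace
#'
#' @param object A `pso_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pso_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$iteration, y = .data$gbest_fitness)) +
    geom_line() +
    labs(x = "iteration", y = "global-best fitness",
         title = sprintf("PSO trace (%s)", object$method))
}
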