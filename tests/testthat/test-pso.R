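test_that("shrinkage factor follows the linear schedule and its domain", {
  cfg <- pso_config(n_max = 100, p_max = 0.9, p_min = 0.4)
  expect_identical(shrinkage_factor(0, cfg), 0.9)
  expect_identical(shrinkage_factor(100, cfg), 0.4)
  expect_equal(shrinkage_factor(50, cfg), 0.65)
  expect_true(all(shrinkage_factor(0:100, cfg) >= 0.4))
  expect_true(all(shrinkage_factor(0:100, cfg) <= 0.9))
  expect_error(shrinkage_factor(101, cfg), class = "ipsoseg_error_domain")
  expect_error(shrinkage_factor(-1, cfg), class = "ipsoseg_error_domain")
})

test_that("shrinkage factor is affine in the iteration number", {
  cfg <- pso_config(n_max = 100, p_max = 0.85, p_min = 0.3)
  for (pair in list(c(0, 100), c(10, 90), c(4, 30), c(20, 20))) {
    mid <- sum(pair) / 2
    expect_equal(
      shrinkage_factor(pair[1], cfg) + shrinkage_factor(pair[2], cfg),
      2 * shrinkage_factor(mid, cfg),
      tolerance = 1e-15
    )
  }
})

test_that("config invariants are enforced", {
  expect_error(pso_config(swarm_size = 1), class = "ipsoseg_error_parameter")
  expect_error(pso_config(p_max = 0.3, p_min = 0.4),
               class = "ipsoseg_error_parameter")
  expect_error(pso_config(p_min = 0), class = "ipsoseg_error_parameter")
  expect_error(pso_config(c1 = 0, c2 = 0), class = "ipsoseg_error_parameter")
  expect_error(search_bounds(c(0, 5), c(10, 5)),
               class = "ipsoseg_error_parameter")
})

test_that("velocity update follows the constriction form and clamps", {
  cfg <- pso_config(inertia_weight = 1, c1 = 2, c2 = 0, v_max = 10)
  # identity: no attraction, factor 1 keeps the velocity
  p <- list(position = 5, velocity = 2, pbest_position = 5)
  expect_equal(velocity_update(p, 5, 1, pso_config(c1 = 0, c2 = 2, v_max = 10),
                               r1 = 1, r2 = 1), 2)
  # equilibrium: everything at rest at the best point stays at rest
  p0 <- list(position = 7, velocity = 0, pbest_position = 7)
  expect_equal(velocity_update(p0, 7, 0.65, cfg, r1 = 0.3, r2 = 0.9), 0)
  # hand arithmetic: 0.5 * (1*2 + 2*1*3) = 4
  ph <- list(position = 0, velocity = 2, pbest_position = 3)
  expect_equal(velocity_update(ph, 0, 0.5, cfg, r1 = 1, r2 = 1), 4)
  # clamped at v_max
  pf <- list(position = 0, velocity = 100, pbest_position = 0)
  expect_equal(velocity_update(pf, 0, 1, cfg, r1 = 0, r2 = 0), 10)
  expect_error(velocity_update(ph, c(0, 0), 0.5, cfg, r1 = 1, r2 = 1),
               class = "ipsoseg_error_contract")
})

test_that("position update clamps into bounds and zeroes residual velocity", {
  b <- search_bounds(0, 255)
  expect_equal(position_update(list(position = 10), 5, b)$position, 15)
  up <- position_update(list(position = 250), 10, b)
  expect_equal(up$position, 255)
  expect_equal(up$velocity, 0)
  lo <- position_update(list(position = 0), -1, b)
  expect_equal(lo$position, 0)
  expect_equal(lo$velocity, 0)
})

test_that("swarm initialization is seeded, bounded and scores a constant", {
  cfg <- pso_config(swarm_size = 5, seed = 11)
  b <- search_bounds(0, 255)
  s1 <- initialize_swarm(cfg, b, function(x) 3)
  s2 <- initialize_swarm(cfg, b, function(x) 3)
  expect_identical(s1, s2)
  expect_true(all(s1$positions >= 0 & s1$positions <= 255))
  expect_equal(s1$gbest_fitness, 3)
  expect_equal(s1$gbest_fitness, max(s1$pbest_fitness))
  expect_error(initialize_swarm(cfg, b, function(x) NaN),
               class = "ipsoseg_error_evaluation")
})

test_that("one swarm step is elitist and respects the fixed point", {
  cfg <- pso_config(swarm_size = 6, seed = 3)
  b <- search_bounds(0, 255)
  st <- initialize_swarm(cfg, b, quadratic_objective)
  st2 <- withr::with_seed(1, swarm_step(st, cfg, b, quadratic_objective))
  expect_gte(st2$gbest_fitness, st$gbest_fitness)
  expect_identical(st2$iteration, 1L)
  # every particle parked at the optimum with zero velocity stays put
  fixed <- st
  fixed$positions[] <- 128
  fixed$velocities[] <- 0
  fixed$pbest_positions[] <- 128
  fixed$pbest_fitness[] <- 0
  fixed$gbest_position <- 128
  fixed$gbest_fitness <- 0
  moved <- withr::with_seed(2, swarm_step(fixed, cfg, b, quadratic_objective))
  expect_equal(moved$positions, fixed$positions)
  expect_identical(moved$iteration, 1L)
  at_max <- st
  at_max$iteration <- cfg$n_max
  expect_error(swarm_step(at_max, cfg, b, quadratic_objective),
               class = "ipsoseg_error_domain")
})

test_that("both optimizers find the 1-D quadratic optimum deterministically", {
  b <- search_bounds(0, 255)
  cfg <- pso_config(swarm_size = 20, n_max = 100, seed = 1)
  for (fn in list(pso_optimize, pso_optimize_standard)) {
    res <- fn(quadratic_objective, b, cfg)
    expect_lte(abs(res$best_fitness), 0.25)
    expect_lte(abs(res$best_position - 128), 0.5)
    expect_true(all(diff(res$fitness_trace) >= 0))
    expect_length(res$fitness_trace, res$iterations_run)
    expect_identical(res, fn(quadratic_objective, b, cfg))
  }
})

test_that("quadratic argmax is located within 0.5 in at least 99 of 100 seeded runs", {
  b <- search_bounds(0, 255)
  hits <- sum(vapply(1:100, function(s) {
    res <- pso_optimize(quadratic_objective, b,
                        pso_config(swarm_size = 20, n_max = 100, seed = s))
    abs(res$best_position - 128) <= 0.5
  }, logical(1)))
  expect_gte(hits, 99)
})

test_that("particles remain in bounds across many random steps", {
  b <- search_bounds(c(-3, 0), c(2, 10))
  cfg <- pso_config(swarm_size = 10, n_max = 40, seed = 5)
  rosen <- function(x) -( (1 - x[1])^2 + 5 * (x[2] - x[1]^2)^2 )
  total_records <- 0L
  withr::with_seed(99, {
    st <- initialize_swarm(cfg, b, rosen, seed = NULL)
    for (i in seq_len(cfg$n_max)) {
      st <- swarm_step(st, cfg, b, rosen)
      expect_true(all(st$positions[, 1] >= -3 & st$positions[, 1] <= 2))
      expect_true(all(st$positions[, 2] >= 0 & st$positions[, 2] <= 10))
      total_records <- total_records + cfg$swarm_size
    }
  })
  expect_gte(total_records, 400L)
})

test_that("early stall stops the run and flags it", {
  b <- search_bounds(0, 255)
  cfg <- pso_config(swarm_size = 15, n_max = 100, seed = 2,
                    stall_tolerance = 1e-12, stall_window = 10)
  res <- pso_optimize(quadratic_objective, b, cfg)
  expect_true(res$converged_early)
  expect_lt(res$iterations_run, 100)
})

test_that("comparison harness tidies both optimizers' traces", {
  b <- search_bounds(0, 255)
  cfg <- pso_config(swarm_size = 10, n_max = 30, seed = 4)
  tr <- compare_pso(quadratic_objective, b, cfg)
  expect_setequal(unique(tr$method), c("ipso", "standard"))
  expect_equal(nrow(tr), 60)
  expect_true(all(tr$iteration %in% 1:30))
  g <- glance(pso_optimize(quadratic_objective, b, cfg))
  expect_identical(g$method, "ipso")
})
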