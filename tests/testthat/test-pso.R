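test_that("velocity update follows the inertia + attraction rule with clamping", {
  cfg <- pso_config()
  x <- c(2, 3)
  # zero displacement: attraction terms vanish, only inertia remains
  v <- pso_velocity(c(1, -2), x, x, x, inertia = 0.7, cfg, r1 = c(1, 1), r2 = c(0.2, 0.9))
  expect_equal(v, 0.7 * c(1, -2))
  # hand-computed attraction: inertia 0, c1 = c2 = 2, dt = 1, draws all 1
  v <- pso_velocity(c(0, 0), c(0, 0), c(1, 0), c(0, 1), inertia = 0, cfg,
                    r1 = c(1, 1), r2 = c(1, 1))
  expect_equal(v, c(2, 2))
  # clamp contract: components always inside [-v_max, v_max]
  set.seed(6)
  for (i in 1:25) {
    v <- pso_velocity(runif(2, -20, 20), runif(2, 0, 10), runif(2, 0, 10),
                      runif(2, 0, 10), runif(1, 0, 1), cfg, runif(2), runif(2))
    expect_true(all(abs(v) <= cfg$v_max))
  }
  expect_error(pso_velocity(c(0, 0), c(0, 0, 0), c(1, 0), c(0, 1), 0.5, cfg,
                            c(1, 1), c(1, 1)), "dimension")
})

test_that("position update advances, clips to bounds and zeroes clipped velocity", {
  cfg <- pso_config()   # bounds [0.1, 9.9]^2
  upd <- pso_position(c(5, 5), c(0, 0), cfg)
  expect_equal(upd$position, c(5, 5))
  expect_equal(upd$velocity, c(0, 0))
  upd <- pso_position(c(9.8, 5), c(1, 0), cfg)
  expect_equal(upd$position, c(9.9, 5))
  expect_equal(upd$velocity, c(0, 0))
  upd <- pso_position(c(3, 4), c(0.5, -0.5), cfg)
  expect_equal(upd$position, c(3.5, 3.5))
  expect_equal(upd$velocity, c(0.5, -0.5))
  expect_error(pso_position(c(1, 2, 3), c(0, 0, 0), cfg), "dimension")
})

test_that("the optimizer is deterministic with a monotone best-so-far trace", {
  cfg <- pso_config(max_iter = 40, seed = 7,
                    bounds = rbind(c(0, 0), c(10, 10)))
  f <- function(p) -sum((p - c(3, 4))^2)
  r1 <- pso_optimize(f, cfg)
  r2 <- pso_optimize(f, cfg)
  expect_identical(r1$fitness_trace, r2$fitness_trace)
  expect_identical(r1$best_position, r2$best_position)
  expect_true(all(diff(r1$fitness_trace) >= 0))
  expect_equal(r1$best_fitness, r1$fitness_trace[length(r1$fitness_trace)])
  expect_equal(r1$best_fitness, f(r1$best_position))
  expect_equal(r1$iterations_run, 40L)
})

test_that("every evaluated position stays inside the bounds", {
  seen <- list()
  f <- function(p) {
    seen[[length(seen) + 1L]] <<- p
    -sum(p^2)
  }
  cfg <- pso_config(swarm_size = 6, max_iter = 25, seed = 3,
                    bounds = rbind(c(-1, 2), c(1, 5)))
  pso_optimize(f, cfg)
  pos <- do.call(rbind, seen)
  expect_true(all(pos[, 1] >= -1 & pos[, 1] <= 1))
  expect_true(all(pos[, 2] >= 2 & pos[, 2] <= 5))
})

test_that("a one-particle, one-iteration run returns its initial sample", {
  f <- function(p) -sum((p - 5)^2)
  cfg <- pso_config(swarm_size = 1, max_iter = 1, seed = 11,
                    bounds = rbind(c(0, 0), c(10, 10)))
  r <- pso_optimize(f, cfg)
  # with zero initial velocity and p_best = g_best = x, the particle cannot move
  expect_equal(r$best_fitness, f(r$best_position))
  expect_length(r$fitness_trace, 1L)
})

test_that("the optimizer recovers the optimum of a concave quadratic", {
  f <- function(p) -((p[1] - 3)^2 + (p[2] - 4)^2)
  hits <- 0L
  for (s in 1:5) {
    r <- pso_optimize(f, pso_config(seed = s, bounds = rbind(c(0, 0), c(10, 10))))
    if (max(abs(r$best_position - c(3, 4))) < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("fitness failures propagate with the offending position attached", {
  f <- function(p) if (p[1] > 0) stop("boom") else 0
  cfg <- pso_config(swarm_size = 2, max_iter = 2, seed = 1)
  expect_error(pso_optimize(f, cfg), "position")
})

test_that("the optimizer leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(pso_optimize(function(p) -sum(p^2), pso_config(max_iter = 3, seed = 9)))
  expect_identical(runif(1), before)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(pso_config(swarm_size = 0), "positive")
  expect_error(pso_config(inertia_max = 0.3, inertia_min = 0.5), "inertia")
  expect_error(pso_config(v_max = 0), "positive")
  expect_error(pso_config(bounds = rbind(c(5, 5), c(1, 9))), "bounds")
})
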