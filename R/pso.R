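#' Particle swarm optimizer configuration
#'
#' Hyperparameters for the PSO run that selects the incomplete-Beta shape
#' parameters. Defaults follow standard practice for this application: swarm
#' size N = 10, 100 iterations, acceleration constants c1 = c2 = 2, inertia
#' weight decaying linearly from 0.9 to 0.4, velocity clamp 5, and the search
#' box \eqn{[0.1, 9.9]^2} — a closed box strictly inside the transform's open
#' (0, 10) parameter domain, avoiding the endpoint singularities of the Beta
#' density when a shape parameter drops below 1.
#'
#' @param swarm_size Positive integer N.
#' @param max_iter Positive integer; the optimizer always runs exactly this
#'   many iterations (callers inspect the fitness trace for convergence).
#' @param c1,c2 Nonnegative acceleration constants (cognitive / social).
#' @param inertia_max,inertia_min Inertia weight bounds; decayed linearly.
#' @param v_max Positive velocity clamp, applied per component.
#' @param bounds 2 x d matrix, row 1 = lower, row 2 = upper bounds.
#' @param seed Integer seed for the optimizer's random stream.
#' @param time_step Positive \eqn{\Delta t}; default 1.
#' @return A `pso_config` list.
#' @export
pso_config <- function(swarm_size = 10L, max_iter = 100L, c1 = 2, c2 = 2,
                       inertia_max = 0.9, inertia_min = 0.4, v_max = 5,
                       bounds = rbind(lower = c(0.1, 0.1),
                                      upper = c(9.9, 9.9)),
                       seed = 0L, time_step = 1) {
  swarm_size <- as.integer(swarm_size)
  max_iter <- as.integer(max_iter)
  if (is.na(swarm_size) || swarm_size < 1L) {
    stop("`swarm_size` must be a positive integer", call. = FALSE)
  }
  if (is.na(max_iter) || max_iter < 1L) {
    stop("`max_iter` must be a positive integer", call. = FALSE)
  }
  if (c1 < 0 || c2 < 0) stop("`c1` and `c2` must be nonnegative", call. = FALSE)
  if (inertia_min > inertia_max) {
    stop("`inertia_min` must not exceed `inertia_max`", call. = FALSE)
  }
  if (!is.finite(v_max) || v_max <= 0) {
    stop("`v_max` must be positive", call. = FALSE)
  }
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L || ncol(bounds) < 1L || any(bounds[1, ] > bounds[2, ])) {
    stop("`bounds` must be a 2 x d matrix with lower <= upper per dimension",
         call. = FALSE)
  }
  if (!is.finite(time_step) || time_step <= 0) {
    stop("`time_step` must be positive", call. = FALSE)
  }
  structure(list(swarm_size = swarm_size, max_iter = max_iter, c1 = c1, c2 = c2,
                 inertia_max = inertia_max, inertia_min = inertia_min,
                 v_max = v_max, bounds = bounds, seed = as.integer(seed),
                 time_step = time_step),
            class = "pso_config")
}

#' PSO velocity update
#'
#' One particle's velocity update:
#' \deqn{v^{k+1} = \omega v^k + c_1 r_1 (p - x)/\Delta t + c_2 r_2 (g - x)/\Delta t,}
#' with independent uniform draws \eqn{r_1, r_2} per dimension, followed by
#' clamping each component to \eqn{[-v_{max}, v_{max}]}.
#'
#' @param v,x,p_best,g_best Numeric vectors of equal length: current velocity,
#'   position, personal best and global best.
#' @param inertia Current inertia weight \eqn{\omega}.
#' @param config A [pso_config()].
#' @param r1,r2 Uniform draws in \eqn{[0,1]}, one per dimension.
#' @return The clamped new velocity vector.
#' @export
pso_velocity <- function(v, x, p_best, g_best, inertia, config, r1, r2) {
  d <- length(x)
  if (length(v) != d || length(p_best) != d || length(g_best) != d ||
      length(r1) != d || length(r2) != d) {
    stop("velocity-update vectors must share one dimension", call. = FALSE)
  }
  vn <- inertia * v +
    config$c1 * r1 * (p_best - x) / config$time_step +
    config$c2 * r2 * (g_best - x) / config$time_step
  pmin(pmax(vn, -config$v_max), config$v_max)
}

#' PSO position update
#'
#' Advances a particle by \eqn{x^{k+1} = x^k + v^k \Delta t}, clips the result
#' to the search box, and zeroes the velocity component of any clipped
#' dimension so boundary particles do not push outward on the next step.
#'
#' @param x,v Position and velocity vectors of equal length.
#' @param config A [pso_config()].
#' @return A list with elements `position` and `velocity`.
#' @export
pso_position <- function(x, v, config) {
  if (length(x) != length(v) || length(x) != ncol(config$bounds)) {
    stop("position-update vectors must share the search-space dimension",
         call. = FALSE)
  }
  xn <- x + v * config$time_step
  lo <- config$bounds[1, ]
  hi <- config$bounds[2, ]
  clipped <- xn < lo | xn > hi
  xn <- pmin(pmax(xn, lo), hi)
  v[clipped] <- 0
  list(position = xn, velocity = v)
}

#' Run the particle swarm optimizer
#'
#' Maximizes `fitness` over the configured box. Positions are initialized
#' uniformly in the bounds from the seeded stream and velocities at zero; the
#' inertia weight decays linearly from `inertia_max` to `inertia_min` over the
#' iterations; personal and global bests track the maximum fitness seen.
#' Exactly `max_iter` iterations are run, and identical `(seed, config,
#' fitness)` give bit-identical results. The caller's RNG state is left
#' untouched.
#'
#' @param fitness Function mapping a position vector to a scalar fitness
#'   (higher is better), defined everywhere inside the bounds.
#' @param config A [pso_config()].
#' @return A `pso_result` list: `best_position`, `best_fitness`,
#'   `fitness_trace` (best-so-far per iteration, nondecreasing),
#'   `iterations_run`, `seed`.
#' @examples
#' res <- pso_optimize(function(p) -sum((p - c(3, 4))^2),
#'                     pso_config(bounds = rbind(c(0, 0), c(10, 10)), seed = 1))
#' res$best_position
#' @export
pso_optimize <- function(fitness, config = pso_config()) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  d <- ncol(config$bounds)
  lo <- config$bounds[1, ]
  hi <- config$bounds[2, ]
  n <- config$swarm_size

  eval_fit <- function(pos) {
    f <- tryCatch(fitness(pos), error = function(e) {
      stop(sprintf("fitness evaluation failed at position (%s): %s",
                   paste(signif(pos, 6), collapse = ", "),
                   conditionMessage(e)), call. = FALSE)
    })
    if (!is.numeric(f) || length(f) != 1L || is.na(f)) {
      stop(sprintf("fitness must return a single non-NA number (position %s)",
                   paste(signif(pos, 6), collapse = ", ")), call. = FALSE)
    }
    as.numeric(f)
  }

  X <- matrix(0, n, d)
  for (i in seq_len(n)) X[i, ] <- lo + stats::runif(d) * (hi - lo)
  V <- matrix(0, n, d)
  fit <- apply(X, 1L, eval_fit)

  P <- X                      # personal bests
  p_fit <- fit
  g_i <- which.max(p_fit)
  G <- P[g_i, ]
  g_fit <- p_fit[g_i]

  trace <- numeric(config$max_iter)
  for (k in seq_len(config$max_iter)) {
    w <- config$inertia_max -
      (config$inertia_max - config$inertia_min) * k / config$max_iter
    for (i in seq_len(n)) {
      r1 <- stats::runif(d)
      r2 <- stats::runif(d)
      v <- pso_velocity(V[i, ], X[i, ], P[i, ], G, w, config, r1, r2)
      upd <- pso_position(X[i, ], v, config)
      X[i, ] <- upd$position
      V[i, ] <- upd$velocity
      f <- eval_fit(X[i, ])
      if (f > p_fit[i]) {
        p_fit[i] <- f
        P[i, ] <- X[i, ]
        if (f > g_fit) {
          g_fit <- f
          G <- X[i, ]
        }
      }
    }
    trace[k] <- g_fit
  }

  structure(list(best_position = G, best_fitness = g_fit,
                 fitness_trace = trace, iterations_run = config$max_iter,
                 seed = config$seed),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result> best fitness %.6g at (%s) after %d iterations (seed %d)\n",
              x$best_fitness, paste(signif(x$best_position, 6), collapse = ", "),
              x$iterations_run, x$seed))
  invisible(x)
}
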