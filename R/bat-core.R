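#' Rosenbrock benchmark function
#'
#' The classic banana-valley benchmark,
#' \eqn{f(x) = \sum_{i=1}^{D-1} [100 (x_{i+1} - x_i^2)^2 + (x_i - 1)^2]},
#' used both as the optimizer test bench and as the position-blind fitness
#' mode of [select_features()]. Minimum 0 at \eqn{x = (1, \dots, 1)}.
#'
#' @param x Numeric vector of length \eqn{D \ge 2}, or a matrix with one
#'   position per row (all rows evaluated at once).
#' @return A single value, or one value per row for matrix input.
#' @examples
#' rosenbrock(c(1, 1, 1))   # 0, the global minimum
#' rosenbrock(c(-1.2, 1))   # 24.2
#' @export
rosenbrock <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2L) stop("rosenbrock needs dimension >= 2", call. = FALSE)
    d <- ncol(x)
    return(rowSums(100 * (x[, -1L, drop = FALSE] - x[, -d, drop = FALSE]^2)^2 +
                     (x[, -d, drop = FALSE] - 1)^2))
  }
  if (length(x) < 2L) stop("rosenbrock needs dimension >= 2", call. = FALSE)
  d <- length(x)
  sum(100 * (x[-1L] - x[-d]^2)^2 + (x[-d] - 1)^2)
}
attr(rosenbrock, "batecg_vectorized") <- TRUE

#' Frequency draw for the bat move
#'
#' @param fmin,fmax Frequency band, `fmin <= fmax`.
#' @param u Uniform draw(s) in \[0, 1\].
#' @return `fmin + (fmax - fmin) * u`.
#' @export
draw_frequency <- function(fmin, fmax, u) {
  if (fmin > fmax) stop("fmin must not exceed fmax", call. = FALSE)
  fmin + (fmax - fmin) * u
}

#' Velocity update of the bat move
#'
#' `v' = v + (x - x_gbest) * f`. Note the sign: the published update pulls the
#' velocity along `x - x_gbest`, the opposite of the classical bat-algorithm
#' convention; set `classic = TRUE` for the conventional `(x_gbest - x) * f`.
#'
#' @param v,x,x_gbest Numeric vectors of equal length.
#' @param f Frequency (scalar).
#' @param classic Flip to the classical sign convention.
#' @export
update_velocity <- function(v, x, x_gbest, f, classic = FALSE) {
  if (length(v) != length(x) || length(x) != length(x_gbest))
    stop("velocity/position/global-best length mismatch", call. = FALSE)
  if (classic) v + (x_gbest - x) * f else v + (x - x_gbest) * f
}

#' Position update with hard clamping to the bounds box
#'
#' @param x,v Numeric vectors of equal length.
#' @param bounds Two-column matrix (lo, hi), one row per dimension.
#' @export
update_position <- function(x, v, bounds) {
  if (length(x) != length(v)) stop("position/velocity length mismatch", call. = FALSE)
  clamp_bounds(x + v, bounds)
}

clamp_bounds <- function(x, bounds) {
  if (is.matrix(x)) {
    lo <- matrix(bounds[, 1L], nrow(x), ncol(x), byrow = TRUE)
    hi <- matrix(bounds[, 2L], nrow(x), ncol(x), byrow = TRUE)
  } else {
    lo <- bounds[, 1L]
    hi <- bounds[, 2L]
  }
  pmin(pmax(x, lo), hi)
}

#' Scalar local search step around the global best
#'
#' `x_new = x_gbest + eps * A_bar`, where `A_bar` is the population-average
#' loudness and `eps` is a uniform draw per dimension in \[-1, 1\].
#'
#' @param x_gbest Global-best position.
#' @param A_bar Average loudness (> 0).
#' @param epsilon Per-dimension draws in \[-1, 1\].
#' @param bounds Optional bounds matrix for clamping.
#' @export
local_search_ba <- function(x_gbest, A_bar, epsilon, bounds = NULL) {
  stopifnot(A_bar > 0)
  out <- x_gbest + epsilon * A_bar
  if (!is.null(bounds)) out <- clamp_bounds(out, bounds)
  out
}

#' Loudness decay on an accepted update
#'
#' @param A Loudness (> 0).
#' @param alpha Decay factor in (0, 1).
#' @export
decay_loudness <- function(A, alpha) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  alpha * A
}

#' Pulse-rate growth after t accepted updates
#'
#' `r(t) = r0 * (1 - exp(-gamma * t))`: zero at t = 0, saturating at r0.
#'
#' @param r0 Asymptotic pulse rate in (0, 1\].
#' @param gamma Growth constant (> 0).
#' @param t Accepted-update count (>= 0).
#' @export
grow_pulse_rate <- function(r0, gamma, t) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  r0 * (1 - exp(-gamma * t))
}

#' Per-dimension local search of the improved bat algorithm
#'
#' Each dimension j of bat i is perturbed independently: when the gate draw
#' exceeds that dimension's pulse rate, `x'_j = alpha * base_j + eps_j * Abar_j`
#' (Abar_j the population-average loudness of dimension j); otherwise the
#' dimension keeps the bat's own value. This is the exploration mechanism that
#' distinguishes the improved variant: loudness and pulse rate act per
#' dimension, so exploration and exploitation run simultaneously across
#' coordinates instead of being gated bat-wide.
#'
#' @param base Base position (global best by default in the engine).
#' @param x_i The bat's own position (kept on ungated dimensions).
#' @param A_bar_dims Per-dimension population-average loudness.
#' @param r_i_dims The bat's per-dimension pulse rates.
#' @param alpha Shrink factor applied to the base.
#' @param gates Uniform draws in \[0, 1\], one per dimension.
#' @param epsilon Uniform draws in \[-1, 1\], one per dimension.
#' @param bounds Optional bounds matrix for clamping.
#' @return List with `position` and logical `gated` per dimension.
#' @export
local_search_iba <- function(base, x_i, A_bar_dims, r_i_dims, alpha,
                             gates, epsilon, bounds = NULL) {
  d <- length(x_i)
  stopifnot(length(base) == d, length(A_bar_dims) == d, length(r_i_dims) == d,
            length(gates) == d, length(epsilon) == d)
  gated <- gates > r_i_dims
  out <- x_i
  out[gated] <- alpha * base[gated] + epsilon[gated] * A_bar_dims[gated]
  if (!is.null(bounds)) out <- clamp_bounds(out, bounds)
  list(position = out, gated = gated)
}

#' Per-dimension loudness update (improved variant)
#'
#' Gated dimensions decay by `alpha`; ungated dimensions are untouched.
#' @param A_ij Loudness value(s).
#' @param gated Logical flag(s).
#' @param alpha Decay factor in (0, 1).
#' @export
update_loudness_iba <- function(A_ij, gated, alpha) {
  ifelse(gated, decay_loudness(A_ij, alpha), A_ij)
}

#' Per-dimension pulse-rate update (improved variant)
#'
#' Gated dimensions jump to `r0 * (1 - exp(-gamma * t))`; ungated dimensions
#' are untouched. The published piecewise form prints a positive exponent,
#' which diverges; the saturating negative exponent (consistent with the
#' scalar rule) is used.
#'
#' @param r_ij Pulse-rate value(s).
#' @param gated Logical flag(s).
#' @param r0,gamma,t As in [grow_pulse_rate()].
#' @export
update_pulse_iba <- function(r_ij, gated, r0, gamma, t) {
  ifelse(gated, grow_pulse_rate(r0, gamma, t), r_ij)
}

#' Swarm configuration
#'
#' Bundles every tunable of the optimizer engines. Defaults follow the running
#' text of the source method: 30 generations, frequency band \[0, 2\],
#' `alpha = gamma = 0.95`, asymptotic pulse rate `r0 = 0.2`, initial loudness
#' uniform in \[1, 3\]. Population defaults to 25 (a practical test-bench
#' size; the original experiment used 2086 bats).
#'
#' @param dim Problem dimension D.
#' @param pop_size Number of bats (>= 2).
#' @param generations Iterations to run (>= 0).
#' @param fmin,fmax Frequency band.
#' @param alpha Loudness decay factor in (0, 1).
#' @param gamma Pulse-rate growth constant (> 0).
#' @param r0 Asymptotic pulse rate in (0, 1\].
#' @param A_init Length-2 range for initial loudness, `0 < A_min <= A_max`.
#' @param bounds Search box: length-2 vector recycled over dimensions, or a
#'   D x 2 matrix of (lo, hi) rows.
#' @param seed Integer seed; every random draw of a run flows from it.
#' @param local_base Base point of the per-dimension local search: the global
#'   best (`"best"`, default) or the bat's own position (`"self"`).
#' @param classic_velocity Use the classical velocity sign convention.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(dim, pop_size = 25L, generations = 30L,
                         fmin = 0, fmax = 2, alpha = 0.95, gamma = 0.95,
                         r0 = 0.2, A_init = c(1, 3), bounds = c(-5, 5),
                         seed = 1L, local_base = c("best", "self"),
                         classic_velocity = FALSE) {
  local_base <- match.arg(local_base)
  dim <- as.integer(dim)
  pop_size <- as.integer(pop_size)
  generations <- as.integer(generations)
  if (dim < 1L) stop("dim must be >= 1", call. = FALSE)
  if (pop_size < 2L) stop("pop_size must be >= 2", call. = FALSE)
  if (generations < 0L) stop("generations must be >= 0", call. = FALSE)
  if (fmin > fmax) stop("fmin must not exceed fmax", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (!(r0 > 0 && r0 <= 1)) stop("r0 must lie in (0, 1]", call. = FALSE)
  if (length(A_init) != 2L || A_init[1L] <= 0 || A_init[2L] < A_init[1L])
    stop("A_init must be a range with A_max >= A_min > 0", call. = FALSE)
  if (is.matrix(bounds)) {
    if (nrow(bounds) != dim || ncol(bounds) != 2L)
      stop("bounds matrix must be dim x 2", call. = FALSE)
  } else {
    if (length(bounds) != 2L) stop("bounds must be length 2 or dim x 2", call. = FALSE)
    bounds <- matrix(bounds, nrow = dim, ncol = 2L, byrow = TRUE)
  }
  if (any(bounds[, 1L] > bounds[, 2L]))
    stop("each bounds row must satisfy lo <= hi", call. = FALSE)
  structure(list(
    dim = dim, pop_size = pop_size, generations = generations,
    fmin = fmin, fmax = fmax, alpha = alpha, gamma = gamma, r0 = r0,
    A_init = as.numeric(A_init), bounds = bounds, seed = as.integer(seed),
    local_base = local_base, classic_velocity = isTRUE(classic_velocity)
  ), class = "swarm_config")
}

#' @export
print.swarm_config <- function(x, ...) {
  cat(sprintf(
    "Swarm config: %d bats, D=%d, %d generations, f in [%g, %g], alpha=%g, gamma=%g, r0=%g, seed=%d\n",
    x$pop_size, x$dim, x$generations, x$fmin, x$fmax, x$alpha, x$gamma, x$r0, x$seed))
  invisible(x)
}

eval_objective <- function(objective, X) {
  if (isTRUE(attr(objective, "batecg_vectorized"))) {
    fit <- objective(X)
  } else {
    fit <- vapply(seq_len(nrow(X)), function(i) objective(X[i, ]), numeric(1L))
  }
  bad <- which(!is.finite(fit))
  if (length(bad))
    stop(sprintf("objective returned a non-finite value for bat %d", bad[1L]),
         call. = FALSE)
  fit
}

#' Initialize a bat swarm
#'
#' Positions uniform in the bounds box, velocities zero, loudness uniform in
#' `A_init` (one scalar per bat in `"ba"` mode, one value per bat and
#' dimension in `"iba"` mode), pulse rates at their stated initial value `r0`
#' (they dip to the Eq.-6 curve after a bat's first accepted update and
#' saturate back toward `r0`). Starting every pulse rate at zero instead
#' deadlocks the standard variant: a bat with r = 0 never local-searches, its
#' divergent frequency moves never improve, so it never accepts and r stays 0.
#' Fitness is evaluated once here, before the first step. Consumes draws from
#' the current RNG state; [run_optimizer()] seeds it from `config$seed`.
#'
#' @param config A [swarm_config()].
#' @param objective Objective function (vector in, scalar out; minimized).
#' @param mode `"ba"` (scalar loudness/pulse per bat) or `"iba"`
#'   (per-dimension loudness/pulse).
#' @return A `bat_swarm` object.
#' @export
init_swarm <- function(config, objective, mode = c("ba", "iba")) {
  mode <- match.arg(mode)
  n <- config$pop_size
  d <- config$dim
  pos <- matrix(stats::runif(n * d), n, d)
  pos <- sweep(sweep(pos, 2L, config$bounds[, 2L] - config$bounds[, 1L], "*"),
               2L, config$bounds[, 1L], "+")
  vel <- matrix(0, n, d)
  if (mode == "ba") {
    A <- stats::runif(n, config$A_init[1L], config$A_init[2L])
    r <- rep(config$r0, n)
    t_acc <- rep(0L, n)
  } else {
    A <- matrix(stats::runif(n * d, config$A_init[1L], config$A_init[2L]), n, d)
    r <- matrix(config$r0, n, d)
    t_acc <- matrix(0L, n, d)
  }
  fitness <- eval_objective(objective, pos)
  ibest <- which.min(fitness)
  structure(list(
    position = pos, velocity = vel, loudness = A, pulse_rate = r,
    t_acc = t_acc, fitness = fitness,
    gbest = pos[ibest, ], gbest_fitness = fitness[ibest],
    config = config, mode = mode, n_accepted = 0L
  ), class = "bat_swarm")
}

#' One generation of the standard bat algorithm
#'
#' Every bat draws a frequency, moves by the velocity/position updates, and
#' with probability equal to its pulse rate replaces the candidate by a local
#' solution around the global best scaled by the average loudness. The
#' candidate is accepted only when an acceptance draw falls below the bat's
#' loudness AND the candidate strictly improves the bat's own fitness; on
#' acceptance the loudness decays and the pulse rate grows (the per-bat
#' accepted-update count is the clock t). The global best is updated from
#' accepted solutions, so the best-so-far fitness never increases.
#'
#' Draw order per step is fixed and documented for reproducibility:
#' frequencies (n), local-search gates, epsilon (n x D), acceptance draws (n).
#'
#' @param swarm A `bat_swarm` from [init_swarm()].
#' @param objective Objective function (minimized).
#' @return The updated swarm, with `n_accepted` set to this step's count.
#' @export
step_ba <- function(swarm, objective) {
  cfg <- swarm$config
  n <- cfg$pop_size
  d <- cfg$dim
  f <- draw_frequency(cfg$fmin, cfg$fmax, stats::runif(n))
  gate <- stats::runif(n)
  eps <- matrix(stats::runif(n * d, -1, 1), n, d)
  acc_draw <- stats::runif(n)

  gb <- matrix(swarm$gbest, n, d, byrow = TRUE)
  dirsign <- if (cfg$classic_velocity) -1 else 1
  swarm$velocity <- swarm$velocity + dirsign * (swarm$position - gb) * f
  cand <- clamp_bounds(swarm$position + swarm$velocity, cfg$bounds)

  A_bar <- mean(swarm$loudness)
  do_local <- gate < swarm$pulse_rate
  if (any(do_local)) {
    loc <- gb[do_local, , drop = FALSE] + eps[do_local, , drop = FALSE] * A_bar
    cand[do_local, ] <- clamp_bounds(loc, cfg$bounds)
  }

  fit_c <- eval_objective(objective, cand)
  accept <- (acc_draw < swarm$loudness) & (fit_c < swarm$fitness)
  if (any(accept)) {
    swarm$position[accept, ] <- cand[accept, , drop = FALSE]
    swarm$fitness[accept] <- fit_c[accept]
    swarm$t_acc[accept] <- swarm$t_acc[accept] + 1L
    swarm$loudness[accept] <- decay_loudness(swarm$loudness[accept], cfg$alpha)
    swarm$pulse_rate[accept] <- grow_pulse_rate(cfg$r0, cfg$gamma, swarm$t_acc[accept])
    ibest <- which.min(swarm$fitness)
    if (swarm$fitness[ibest] < swarm$gbest_fitness) {
      swarm$gbest <- swarm$position[ibest, ]
      swarm$gbest_fitness <- swarm$fitness[ibest]
    }
  }
  swarm$n_accepted <- sum(accept)
  swarm
}

#' One generation of the improved bat algorithm
#'
#' As [step_ba()], except the local search, loudness and pulse rate operate
#' per dimension: after the frequency move, every dimension j of every bat is
#' gated independently (`rand_j > r_ij`) and gated dimensions are redrawn as
#' `alpha * base_j + eps_j * Abar_j`, with `Abar_j` the population-average
#' loudness of that dimension and `base` the global best (or the bat itself,
#' per `config$local_base`). The acceptance rule is unchanged (the bat's mean
#' loudness gates acceptance); on acceptance, only the gated dimensions decay
#' their loudness and grow their pulse rate.
#'
#' @inheritParams step_ba
#' @export
step_iba <- function(swarm, objective) {
  cfg <- swarm$config
  n <- cfg$pop_size
  d <- cfg$dim
  f <- draw_frequency(cfg$fmin, cfg$fmax, stats::runif(n))
  gates <- matrix(stats::runif(n * d), n, d)
  eps <- matrix(stats::runif(n * d, -1, 1), n, d)
  acc_draw <- stats::runif(n)

  gb <- matrix(swarm$gbest, n, d, byrow = TRUE)
  dirsign <- if (cfg$classic_velocity) -1 else 1
  swarm$velocity <- swarm$velocity + dirsign * (swarm$position - gb) * f
  moved <- clamp_bounds(swarm$position + swarm$velocity, cfg$bounds)

  A_bar_dims <- matrix(colMeans(swarm$loudness), n, d, byrow = TRUE)
  gated <- gates > swarm$pulse_rate
  base <- if (cfg$local_base == "best") gb else swarm$position
  cand <- moved
  cand[gated] <- cfg$alpha * base[gated] + eps[gated] * A_bar_dims[gated]
  cand <- clamp_bounds(cand, cfg$bounds)

  fit_c <- eval_objective(objective, cand)
  accept <- (acc_draw < rowMeans(swarm$loudness)) & (fit_c < swarm$fitness)
  if (any(accept)) {
    upd <- gated & accept   # accepted bats update only their gated dimensions
    swarm$position[accept, ] <- cand[accept, , drop = FALSE]
    swarm$fitness[accept] <- fit_c[accept]
    swarm$t_acc[upd] <- swarm$t_acc[upd] + 1L
    swarm$loudness[upd] <- decay_loudness(swarm$loudness[upd], cfg$alpha)
    swarm$pulse_rate[upd] <- grow_pulse_rate(cfg$r0, cfg$gamma, swarm$t_acc[upd])
    ibest <- which.min(swarm$fitness)
    if (swarm$fitness[ibest] < swarm$gbest_fitness) {
      swarm$gbest <- swarm$position[ibest, ]
      swarm$gbest_fitness <- swarm$fitness[ibest]
    }
  }
  swarm$n_accepted <- sum(accept)
  swarm
}

#' Run a bat-algorithm optimization
#'
#' Seeds the RNG from `config$seed`, initializes the swarm, iterates
#' `config$generations` steps of [step_ba()] or [step_iba()], and returns the
#' global best together with a per-iteration trace (iteration 0 is the
#' initial population). Identical config and seed give an identical trace.
#'
#' @param config A [swarm_config()].
#' @param objective Objective function (minimized). Give it attribute
#'   `batecg_vectorized = TRUE` if it accepts a matrix of row-positions.
#' @param mode `"ba"` or `"iba"`.
#' @return A list of class `bat_result`: `best_position`, `best_fitness`,
#'   `trace` (class `optimizer_trace`: data frame plus a `positions`
#'   attribute), and the final `swarm`.
#' @examples
#' cfg <- swarm_config(dim = 2, pop_size = 10, generations = 50, seed = 7)
#' res <- run_optimizer(cfg, rosenbrock, mode = "iba")
#' res$best_fitness
#' @export
run_optimizer <- function(config, objective, mode = c("ba", "iba")) {
  mode <- match.arg(mode)
  set.seed(config$seed)
  swarm <- init_swarm(config, objective, mode)
  g <- config$generations
  it <- integer(g + 1L)
  bf <- numeric(g + 1L)
  ml <- numeric(g + 1L)
  mr <- numeric(g + 1L)
  na <- integer(g + 1L)
  posrec <- matrix(NA_real_, g + 1L, config$dim)
  record <- function(k) {
    it[k] <<- k - 1L
    bf[k] <<- swarm$gbest_fitness
    ml[k] <<- mean(swarm$loudness)
    mr[k] <<- mean(swarm$pulse_rate)
    na[k] <<- swarm$n_accepted
    posrec[k, ] <<- swarm$gbest
  }
  record(1L)
  stepper <- if (mode == "ba") step_ba else step_iba
  if (g > 0L) for (k in seq_len(g)) {
    swarm <- stepper(swarm, objective)
    record(k + 1L)
  }
  trace <- data.frame(iteration = it, best_fitness = bf,
                      mean_loudness = ml, mean_pulse_rate = mr,
                      acceptances = na)
  attr(trace, "positions") <- posrec
  class(trace) <- c("optimizer_trace", "data.frame")
  structure(list(best_position = swarm$gbest,
                 best_fitness = swarm$gbest_fitness,
                 trace = trace, swarm = swarm, mode = mode,
                 config = config),
            class = "bat_result")
}

#' @export
print.bat_result <- function(x, ...) {
  cat(sprintf("%s run: %d generations, best fitness %.6g\n",
              toupper(x$mode), x$config$generations, x$best_fitness))
  invisible(x)
}
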