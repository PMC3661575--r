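#' One-dimensional resource-gradient environment with walls
#'
#' Agents live on the interval \[`x_min`, `x_max`\]; their position fixes
#' the local resource concentration through a monotone non-decreasing
#' gradient. Two forms are provided: `"linear"` (default) interpolates
#' from `F_lo` at the left wall to `F_hi` at the right wall, and
#' `"sigmoid"` follows a logistic curve in x with configurable steepness
#' and midpoint. Walls are hard: an agent stepping past one is relocated
#' onto it.
#'
#' @param x_min,x_max wall positions, x_min < x_max.
#' @param F_lo,F_hi resource concentrations spanned by the gradient,
#'   0 <= F_lo < F_hi.
#' @param gradient `"linear"` or `"sigmoid"`.
#' @param steepness,midpoint logistic parameters (sigmoid form only).
#' @return An object of class `environment_1d`.
#' @export
environment_1d <- function(x_min = 0, x_max = 1, F_lo = 0, F_hi = 4,
                           gradient = c("linear", "sigmoid"),
                           steepness = 10, midpoint = (x_min + x_max) / 2) {
  gradient <- match.arg(gradient)
  stopifnot(x_min < x_max, F_lo >= 0, F_lo < F_hi, steepness > 0)
  structure(list(x_min = x_min, x_max = x_max, F_lo = F_lo, F_hi = F_hi,
                 gradient = gradient, steepness = steepness,
                 midpoint = midpoint),
            class = "environment_1d")
}

grad_code <- function(env) if (env$gradient == "sigmoid") 1L else 0L

grad_params <- function(env) {
  c(env$x_min, env$x_max, env$F_lo, env$F_hi, env$steepness, env$midpoint)
}

#' Resource concentration at a position
#'
#' @param x position(s) within the walls.
#' @param env an [environment_1d()].
#' @return F at `x`; monotone non-decreasing in x.
#' @export
resource_at <- function(x, env = environment_1d()) {
  stopifnot(inherits(env, "environment_1d"))
  if (any(!is.finite(x)) || any(x < env$x_min) || any(x > env$x_max)) {
    stop("position outside the walls", call. = FALSE)
  }
  vapply(x, resource_at_cpp, numeric(1), grad_code(env), grad_params(env))
}

#' Spatial population settings
#'
#' Initial positions are drawn from a flat distribution between the
#' walls; initial metabolite concentrations from a flat distribution over
#' `init_A_range`; each agent's fixed error bias epsilon from a normal
#' distribution with mean 0 and standard deviation `epsilon_sd` (0 gives
#' bias-free agents). All per-agent draws come from an agent-indexed
#' substream of the master seed, so runs are reproducible and the first n
#' agents of a larger population are unchanged.
#'
#' @param n_agents number of agents (>= 1).
#' @param v agent speed (length per time), > 0. The default 0.25 makes the
#'   maximum induced resource rate along a path, `v (F_hi - F_lo) /
#'   (x_max - x_min)`, equal to the abstract actuator's default maximum
#'   rate r_max = 1, so the spatial and non-spatial analyses are
#'   dynamically comparable.
#' @param dt time step, > 0.
#' @param t_end total simulated time.
#' @param epsilon_sd standard deviation of the fixed per-agent error bias
#'   (same units as dF/dt).
#' @param init_A_range flat-distribution window for initial A.
#' @param snapshot_interval time between recorded population snapshots
#'   (0 disables snapshots).
#' @param seed master integer seed.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_agents = 1000L, v = 0.25, dt = 1e-3,
                              t_end = 100, epsilon_sd = 0,
                              init_A_range = c(0.1, 8),
                              snapshot_interval = 10, seed = 1L) {
  stopifnot(n_agents >= 1, v > 0, dt > 0, t_end > 0, epsilon_sd >= 0,
            length(init_A_range) == 2L,
            init_A_range[1] < init_A_range[2], snapshot_interval >= 0)
  structure(list(n_agents = as.integer(n_agents), v = v, dt = dt,
                 t_end = t_end, epsilon_sd = epsilon_sd,
                 init_A_range = init_A_range,
                 snapshot_interval = snapshot_interval,
                 seed = as.integer(seed)),
            class = "population_config")
}

# Per-agent substreams: agent i's initial position, initial A and epsilon
# are drawn under set.seed(seed + i), independent of population size.
init_agents <- function(env, cfg) {
  n <- cfg$n_agents
  x0 <- A0 <- eps <- numeric(n)
  for (i in seq_len(n)) {
    set.seed((cfg$seed + i) %% .Machine$integer.max)
    x0[i] <- stats::runif(1, env$x_min, env$x_max)
    A0[i] <- stats::runif(1, cfg$init_A_range[1], cfg$init_A_range[2])
    eps[i] <- if (cfg$epsilon_sd > 0) stats::rnorm(1, 0, cfg$epsilon_sd) else 0
  }
  data.frame(agent = seq_len(n), x = x0, A = A0, epsilon = eps,
             status = "alive", stringsAsFactors = FALSE)
}

status_labels <- c("alive", "dead_low", "dead_high")

#' Advance a population by one (or more) time steps
#'
#' Each alive agent reads the resource at its position, evaluates its
#' behavioral rate B plus its fixed error bias, moves one step
#' up-gradient when `B + epsilon >= 0` and down-gradient otherwise, is
#' relocated onto a wall if it stepped past one, and updates its
#' metabolite concentration by the metabolism at the local resource
#' level. Agents crossing a death boundary are marked dead and frozen.
#'
#' @param agents data.frame with columns `x`, `A`, `epsilon`, `status`
#'   (as produced by [run_population()]'s `agents` element).
#' @param behavior a [behavior_spec()].
#' @param env an [environment_1d()].
#' @param p a [metabolism_params()] object.
#' @param cfg a [population_config()] (v and dt are used).
#' @param n_steps number of steps to advance.
#' @return The updated agents data.frame.
#' @export
step_population <- function(agents, behavior, env = environment_1d(),
                            p = calibrate_default_params(),
                            cfg = population_config(), n_steps = 1L) {
  stopifnot(is.data.frame(agents),
            all(c("x", "A", "epsilon", "status") %in% names(agents)))
  res <- run_population_cpp(
    agents$x, agents$A, agents$epsilon,
    match(agents$status, status_labels) - 1L,
    behavior_kind_code(behavior$kind), unlist(behavior$params),
    behavior$r_max, p$k_forward, p$k_backward, p$k_decay,
    p$A_death_low, p$A_death_high, grad_code(env), grad_params(env),
    cfg$v, cfg$dt, n_steps * cfg$dt, as.integer(n_steps), 0L)
  agents$x <- res$x
  agents$A <- res$A
  agents$status <- status_labels[res$status + 1L]
  agents
}

#' Run the 1-D spatial population simulation
#'
#' Simulates `cfg$n_agents` chemotaxing agents on the resource gradient
#' for `cfg$t_end` time units, recording population snapshots at the
#' configured interval.
#'
#' @param behavior a [behavior_spec()].
#' @param env an [environment_1d()].
#' @param p a [metabolism_params()] object.
#' @param cfg a [population_config()].
#' @return An object of class `population_run`: list with `agents` (final
#'   per-agent data.frame: initial state, final state, status, number of
#'   direction reversals), `snapshots` (data.frame `time`, `agent`, `x`,
#'   `A`, `A_init`, `status`), `survival` (alive fraction at t_end),
#'   `death_fractions`, and the configs.
#' @examples
#' pr <- run_population(behavior_preset("B1"),
#'                      cfg = population_config(n_agents = 20, t_end = 5,
#'                                              dt = 0.01, seed = 7))
#' pr$survival
#' @export
run_population <- function(behavior, env = environment_1d(),
                           p = calibrate_default_params(),
                           cfg = population_config()) {
  stopifnot(inherits(behavior, "behavior_spec"),
            inherits(env, "environment_1d"),
            inherits(p, "metabolism_params"),
            inherits(cfg, "population_config"))
  init <- init_agents(env, cfg)
  snap_every <- if (cfg$snapshot_interval > 0) {
    max(1L, as.integer(round(cfg$snapshot_interval / cfg$dt)))
  } else 0L
  res <- run_population_cpp(
    init$x, init$A, init$epsilon, rep(0L, cfg$n_agents),
    behavior_kind_code(behavior$kind), unlist(behavior$params),
    behavior$r_max, p$k_forward, p$k_backward, p$k_decay,
    p$A_death_low, p$A_death_high, grad_code(env), grad_params(env),
    cfg$v, cfg$dt, cfg$t_end, 0L, snap_every)
  agents <- data.frame(
    agent = init$agent, x_init = init$x, A_init = init$A,
    epsilon = init$epsilon, x = res$x, A = res$A,
    status = status_labels[res$status + 1L], reversals = res$reversals)
  snapshots <- NULL
  if (snap_every > 0) {
    ns <- length(res$snap_time)
    n <- cfg$n_agents
    snapshots <- data.frame(
      time = rep(res$snap_time, each = n),
      agent = rep(seq_len(n), ns),
      x = as.vector(t(res$snap_x)),
      A = as.vector(t(res$snap_A)),
      A_init = rep(init$A, ns),
      status = status_labels[as.vector(t(res$snap_status)) + 1L])
  }
  surv <- mean(agents$status == "alive")
  structure(list(
    agents = agents, snapshots = snapshots, survival = surv,
    death_fractions = c(dead_low = mean(agents$status == "dead_low"),
                        dead_high = mean(agents$status == "dead_high")),
    behavior = behavior, env = env, params = p, config = cfg
  ), class = "population_run")
}

#' @export
print.population_run <- function(x, ...) {
  cat(sprintf("Spatial run (%s): %d agents, t_end = %g\n",
              x$behavior$kind, x$config$n_agents, x$config$t_end))
  cat(sprintf("  survived %.1f%% (dead_low %.1f%%, dead_high %.1f%%)\n",
              100 * x$survival, 100 * x$death_fractions["dead_low"],
              100 * x$death_fractions["dead_high"]))
  invisible(x)
}

#' Spatial survival fractions of the four controllers
#'
#' Runs [run_population()] for B1..B4 under a shared configuration and
#' returns the survival fraction per controller.
#'
#' @param env an [environment_1d()].
#' @param p a [metabolism_params()] object.
#' @param cfg a [population_config()].
#' @param r_max maximum actuation rate.
#' @return Named numeric vector of survival fractions (B1..B4).
#' @export
compare_spatial_survival <- function(env = environment_1d(),
                                     p = calibrate_default_params(),
                                     cfg = population_config(),
                                     r_max = 1.0) {
  vapply(c("B1", "B2", "B3", "B4"), function(k) {
    run_population(behavior_preset(k, r_max), env, p, cfg)$survival
  }, numeric(1))
}
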