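#' Integrator settings for the coupled metabolism + behavior system
#'
#' The coupled system is integrated with a fixed-step classical
#' Runge-Kutta (RK4) scheme. Death-boundary crossings are detected every
#' step and the crossing time is localized by linear interpolation inside
#' the crossing step, so the event time converges at O(dt). A trajectory
#' stops early once both |dA/dt| and |dF/dt| fall below `steady_tol`
#' (near-equilibrium), or at `t_end`.
#'
#' @param dt integration step (time units), > 0.
#' @param t_end total simulated time, > 0.
#' @param steady_tol near-equilibrium threshold on |dA/dt| and |dF/dt|.
#' @param save_every record the state every `save_every` steps in
#'   trajectory output (grid runs never store trajectories).
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 1e-3, t_end = 100, steady_tol = 1e-6,
                              save_every = 100L) {
  stopifnot(dt > 0, t_end > 0, steady_tol > 0, save_every >= 1)
  structure(list(dt = dt, t_end = t_end, steady_tol = steady_tol,
                 save_every = as.integer(save_every)),
            class = "integrator_config")
}

outcome_labels <- c("survived", "dead_low", "dead_high")

outcome_label <- function(code) outcome_labels[code + 1L]

#' Simulate one trajectory of the coupled system
#'
#' Integrates dA/dt = [metabolic_rate()] together with dF/dt given by the
#' behavior, from the initial state, with absorbing death boundaries at
#' `p$A_death_low` and `p$A_death_high` (contact counts as death; the
#' state is frozen afterwards).
#'
#' @param init_A,init_F initial state (concentrations, >= 0).
#' @param behavior a [behavior_spec()].
#' @param p a [metabolism_params()] object.
#' @param cfg an [integrator_config()].
#' @return An object of class `trajectory_result`: list with `states` (a
#'   data.frame `time`, `A`, `F`), `outcome` (one of `"survived"`,
#'   `"dead_low"`, `"dead_high"`), `time_of_death` (`NA` if survived),
#'   `final_A`, `final_F`, `reached_steady`.
#' @examples
#' tr <- simulate_trajectory(3, 2, behavior_preset("B1"),
#'                           cfg = integrator_config(t_end = 20))
#' tr$outcome
#' @export
simulate_trajectory <- function(init_A, init_F, behavior,
                                p = calibrate_default_params(),
                                cfg = integrator_config()) {
  stopifnot(inherits(behavior, "behavior_spec"),
            inherits(p, "metabolism_params"),
            inherits(cfg, "integrator_config"))
  check_state(init_A, init_F)
  res <- sim_trajectory_cpp(init_A, init_F,
                            behavior_kind_code(behavior$kind),
                            unlist(behavior$params), behavior$r_max,
                            p$k_forward, p$k_backward, p$k_decay,
                            p$A_death_low, p$A_death_high,
                            cfg$dt, cfg$t_end, cfg$steady_tol,
                            cfg$save_every)
  structure(list(
    states = data.frame(time = res$time, A = res$A, F = res$F),
    outcome = outcome_label(res$outcome),
    time_of_death = res$time_of_death,
    final_A = res$final_A, final_F = res$final_F,
    reached_steady = res$reached_steady,
    behavior = behavior, params = p, config = cfg
  ), class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("Trajectory (%s): outcome = %s", x$behavior$kind, x$outcome))
  if (!is.na(x$time_of_death)) cat(sprintf(" at t = %.4g", x$time_of_death))
  cat(sprintf("; final state (A, F) = (%.4g, %.4g)%s\n",
              x$final_A, x$final_F,
              if (isTRUE(x$reached_steady)) " [near-equilibrium]" else ""))
  invisible(x)
}

#' Rectangular lattice of initial conditions
#'
#' @param F_range,A_range length-2 windows for the initial resource and
#'   metabolite concentrations.
#' @param resolution lattice points per axis (>= 2).
#' @return An object of class `initial_grid`.
#' @export
initial_grid <- function(F_range = c(0, 4), A_range = c(0, 8),
                         resolution = 51L) {
  stopifnot(length(F_range) == 2L, length(A_range) == 2L,
            F_range[1] < F_range[2], A_range[1] < A_range[2],
            resolution >= 2)
  structure(list(F_range = F_range, A_range = A_range,
                 resolution = as.integer(resolution)),
            class = "initial_grid")
}

grid_points <- function(grid) {
  Fs <- seq(grid$F_range[1], grid$F_range[2], length.out = grid$resolution)
  As <- seq(grid$A_range[1], grid$A_range[2], length.out = grid$resolution)
  # row-major in F (F varies fastest), matching the lattice-search tie rule
  expand.grid(F_init = Fs, A_init = As, KEEP.OUT.ATTRS = FALSE)
}

#' Map survivable initial conditions over a lattice
#'
#' Simulates one trajectory per lattice cell and records its outcome and
#' final metabolite concentration: the model analogue of plotting which
#' initial (F, A) states a controller steers away from both death
#' boundaries. Cells are independent, so the result does not depend on
#' evaluation order.
#'
#' @param behavior a [behavior_spec()].
#' @param p a [metabolism_params()] object.
#' @param grid an [initial_grid()]; defaults to the reference 51 x 51
#'   lattice over F in \[0, 4\], A in \[0, A_death_high\].
#' @param cfg an [integrator_config()]; the default map configuration uses
#'   dt = 0.01 (maps trade step size for lattice size; see the package
#'   vignette).
#' @return An object of class `survivability_grid`: list with `cells` (a
#'   data.frame `F_init`, `A_init`, `outcome`, `final_A`,
#'   `time_of_death`), the grid, and outcome `proportions`.
#' @examples
#' g <- survivability_map(behavior_preset("B1"),
#'                        grid = initial_grid(resolution = 11),
#'                        cfg = integrator_config(dt = 0.01, t_end = 50))
#' survival_proportion(g)
#' @export
survivability_map <- function(behavior, p = calibrate_default_params(),
                              grid = initial_grid(A_range = c(0, p$A_death_high)),
                              cfg = integrator_config(dt = 0.01)) {
  stopifnot(inherits(behavior, "behavior_spec"),
            inherits(p, "metabolism_params"),
            inherits(grid, "initial_grid"),
            inherits(cfg, "integrator_config"))
  pts <- grid_points(grid)
  res <- sim_grid_cpp(pts$A_init, pts$F_init,
                      behavior_kind_code(behavior$kind),
                      unlist(behavior$params), behavior$r_max,
                      p$k_forward, p$k_backward, p$k_decay,
                      p$A_death_low, p$A_death_high,
                      cfg$dt, cfg$t_end, cfg$steady_tol)
  cells <- data.frame(F_init = pts$F_init, A_init = pts$A_init,
                      outcome = outcome_label(res$outcome),
                      final_A = res$final_A,
                      time_of_death = res$time_of_death)
  prop <- vapply(outcome_labels,
                 function(l) mean(cells$outcome == l), numeric(1))
  structure(list(cells = cells, grid = grid, proportions = prop,
                 behavior = behavior, params = p, config = cfg),
            class = "survivability_grid")
}

#' @export
print.survivability_grid <- function(x, ...) {
  cat(sprintf("Survivability map (%s), %d x %d lattice\n",
              x$behavior$kind, x$grid$resolution, x$grid$resolution))
  cat(sprintf("  survived %.1f%%, dead_low %.1f%%, dead_high %.1f%%\n",
              100 * x$proportions["survived"],
              100 * x$proportions["dead_low"],
              100 * x$proportions["dead_high"]))
  invisible(x)
}

#' @export
as.data.frame.survivability_grid <- function(x, ...) x$cells

#' Fraction of lattice cells survived
#'
#' @param g a [survivability_map()] result.
#' @return survivors / total cells, in \[0, 1\].
#' @export
survival_proportion <- function(g) {
  stopifnot(inherits(g, "survivability_grid"), nrow(g$cells) > 0)
  mean(g$cells$outcome == "survived")
}

#' Survival proportions of the four controllers on a common lattice
#'
#' Runs [survivability_map()] for B1..B4 (published presets) on the same
#' lattice and returns the survival proportion per controller. With the
#' calibrated default metabolism this reproduces the characteristic
#' ordering B4 > B3 > B1 > B2.
#'
#' @param p a [metabolism_params()] object.
#' @param grid an [initial_grid()].
#' @param cfg an [integrator_config()].
#' @param r_max maximum actuation rate shared by all controllers.
#' @return Named numeric vector of survival proportions (B1..B4).
#' @export
compare_survival <- function(p = calibrate_default_params(),
                             grid = initial_grid(A_range = c(0, p$A_death_high)),
                             cfg = integrator_config(dt = 0.01),
                             r_max = 1.0) {
  vapply(c("B1", "B2", "B3", "B4"), function(k) {
    survival_proportion(
      survivability_map(behavior_preset(k, r_max), p, grid, cfg))
  }, numeric(1))
}
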