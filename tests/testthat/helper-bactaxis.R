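# Shared fixtures and independent oracles.

default_p <- calibrate_default_params()

# Random metabolism parameter draw with moderate magnitudes (keeps
# root-residual comparisons on an absolute 1e-10 scale meaningful).
random_params <- function() {
  metabolism_params(k_forward = runif(1, 0.5, 2),
                    k_backward = runif(1, 0.5, 2),
                    k_decay = runif(1, 0.5, 2),
                    A_death_low = 0.1, A_death_high = 8)
}

# Independent root oracle: bracketed uniroot on metabolic_rate in A.
numeric_roots <- function(F, p, upper = 50) {
  f <- function(A) metabolic_rate(A, F, p)
  grid <- seq(1e-6, upper, length.out = 4001)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  vapply(idx, function(i) {
    uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-13)$root
  }, numeric(1))
}

# Holds F fixed: a behavior spec with a null actuator.
null_behavior <- function() behavior_spec("B1", r_max = 0)

# Brute-force viability oracle: integrate at fixed F until death or
# near-equilibrium; living states that die are precarious, the rest viable.
oracle_classify <- function(A, F, p,
                            cfg = integrator_config(dt = 1e-3, t_end = 200)) {
  if (A <= p$A_death_low) return("dead_low")
  if (A >= p$A_death_high) return("dead_high")
  tr <- simulate_trajectory(A, F, null_behavior(), p, cfg)
  if (tr$outcome != "survived") "precarious" else "viable"
}

# deSolve reference integration of the coupled system (independent of the
# package's RK4 path), with death boundaries as root events.
desolve_trajectory <- function(init_A, init_F, behavior, p, t_end,
                               times = seq(0, t_end, by = 0.1)) {
  rhs <- function(t, y, parms) {
    A <- max(y[1], 0); F <- max(y[2], 0)
    dA <- metabolic_rate(A, F, p)
    dF <- behavior_rate(behavior, A, F, dA_dt = dA, p = p)
    list(c(dA, dF))
  }
  rootfun <- function(t, y, parms) {
    c(y[1] - p$A_death_low, y[1] - p$A_death_high)
  }
  deSolve::lsodar(c(A = init_A, F = init_F), times, rhs, parms = NULL,
                  rootfunc = rootfun, rtol = 1e-10, atol = 1e-10)
}
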