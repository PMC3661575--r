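test_that("a viable equilibrium with a matched homeostat is a fixed point", {
  p <- default_p
  F0 <- 1.5
  A0 <- equilibria(F0, p)$stable_root
  b <- behavior_spec("B1", list(theta_F = F0, k_F = 9.4))
  tr <- simulate_trajectory(A0, F0, b, p, integrator_config(t_end = 20))
  expect_identical(tr$outcome, "survived")
  expect_lt(abs(tr$final_A - A0), 1e-6)
  expect_lt(abs(tr$final_F - F0), 1e-6)
  expect_true(tr$reached_steady)
})

test_that("death boundaries are closed and absorbing", {
  p <- default_p
  b <- behavior_preset("B1")
  tr <- simulate_trajectory(p$A_death_low, 2, b, p)
  expect_identical(tr$outcome, "dead_low")
  expect_identical(tr$time_of_death, 0)
  tr <- simulate_trajectory(p$A_death_high, 2, b, p)
  expect_identical(tr$outcome, "dead_high")
  # frozen after death: final state sits on the boundary, trace stops there
  tr <- simulate_trajectory(0.2, 0.1, b, p, integrator_config(t_end = 50))
  expect_identical(tr$outcome, "dead_low")
  expect_equal(tr$final_A, p$A_death_low)
  expect_lt(max(tr$states$time), 50)
  expect_equal(tr$states$A[nrow(tr$states)], p$A_death_low)
})

test_that("trajectory outcome invariants hold across random starts", {
  set.seed(12)
  p <- default_p
  cfg <- integrator_config(dt = 0.01, t_end = 50)
  for (i in 1:40) {
    b <- behavior_preset(sample(c("B1", "B2", "B3", "B4"), 1))
    tr <- simulate_trajectory(runif(1, 0, 8), runif(1, 0, 4), b, p, cfg)
    if (tr$outcome == "survived") {
      expect_true(tr$final_A > p$A_death_low && tr$final_A < p$A_death_high)
      expect_true(is.na(tr$time_of_death))
    } else {
      expect_false(is.na(tr$time_of_death))
      boundary <- if (tr$outcome == "dead_low") p$A_death_low else
        p$A_death_high
      expect_equal(tr$final_A, boundary)
    }
  }
})

test_that("death time converges as the step size is refined", {
  p <- default_p
  b <- behavior_preset("B2")
  t1 <- simulate_trajectory(7, 3.8, b, p,
                            integrator_config(dt = 2e-3))$time_of_death
  t2 <- simulate_trajectory(7, 3.8, b, p,
                            integrator_config(dt = 1e-3))$time_of_death
  expect_false(is.na(t1))
  expect_lt(abs(t1 - t2), 2e-3)
})

test_that("trajectories agree with an independent lsodar integration", {
  p <- default_p
  cfg <- integrator_config(dt = 1e-3, t_end = 10, steady_tol = 1e-12)
  for (k in c("B1", "B3", "B4")) {
    b <- behavior_preset(k)
    tr <- simulate_trajectory(3, 2, b, p, cfg)
    ref <- desolve_trajectory(3, 2, b, p, t_end = 10)
    last <- ref[nrow(ref), ]
    expect_lt(abs(tr$final_A - last[["A"]]), 1e-5)
    expect_lt(abs(tr$final_F - last[["F"]]), 1e-5)
  }
  # death-event time against lsodar's root finder
  b2 <- behavior_preset("B2")
  tr <- simulate_trajectory(7, 3.8, b2, p,
                            integrator_config(dt = 1e-3, t_end = 50))
  ref <- desolve_trajectory(7, 3.8, b2, p, t_end = 50,
                            times = seq(0, 50, by = 0.01))
  t_root <- attr(ref, "troot")
  expect_lt(abs(tr$time_of_death - t_root), 1e-3)
})

test_that("survivability maps partition the lattice and are order-free", {
  p <- default_p
  cfg <- integrator_config(dt = 0.01, t_end = 50)
  g <- survivability_map(behavior_preset("B1"), p,
                         initial_grid(resolution = 11), cfg)
  expect_identical(nrow(g$cells), 121L)
  expect_equal(sum(g$proportions), 1)
  expect_equal(survival_proportion(g),
               1 - g$proportions[["dead_low"]] - g$proportions[["dead_high"]])
  # qualitative structure: survivors in the mid-range, both death modes seen
  expect_gt(survival_proportion(g), 0)
  expect_gt(g$proportions[["dead_low"]], 0)
  expect_gt(g$proportions[["dead_high"]], 0)
  # purity: a permuted evaluation order gives identical per-cell results
  set.seed(8)
  perm <- sample.int(121)
  pts <- as.data.frame(g)[perm, ]
  g2 <- survivability_map(behavior_preset("B1"), p,
                          initial_grid(resolution = 11), cfg)
  expect_identical(as.data.frame(g2)[perm, ], pts)
})

test_that("a null actuator on an all-precarious lattice kills every cell", {
  p <- default_p
  g <- survivability_map(null_behavior(), p,
                         initial_grid(F_range = c(0.01, 0.5),
                                      A_range = c(0.2, 2), resolution = 5),
                         integrator_config(dt = 0.01, t_end = 100))
  expect_identical(unique(g$cells$outcome), "dead_low")
  expect_identical(survival_proportion(g), 0)
})

test_that("six reference starts under the rate-of-change controller survive", {
  # the rate-of-change controller steers all reference starts away from
  # both death boundaries
  p <- default_p
  b <- behavior_preset("B3")
  starts <- data.frame(A = c(6.5, 3.0, 7.0, 0.5, 2.0, 1.5),
                       F = c(0.5, 2.0, 1.5, 2.0, 0.25, 2.5))
  for (i in seq_len(nrow(starts))) {
    tr <- simulate_trajectory(starts$A[i], starts$F[i], b, p,
                              integrator_config(dt = 1e-3, t_end = 100))
    expect_identical(tr$outcome, "survived",
                     label = sprintf("start (A=%g, F=%g) outcome",
                                     starts$A[i], starts$F[i]))
  }
})

test_that("survived trajectories end near-steady or at the horizon", {
  set.seed(31)
  p <- default_p
  cfg <- integrator_config(dt = 0.01, t_end = 60, steady_tol = 1e-6)
  for (i in 1:20) {
    tr <- simulate_trajectory(runif(1, 0.5, 7.5), runif(1, 0, 4),
                              behavior_preset("B4"), p, cfg)
    if (tr$outcome == "survived" && tr$reached_steady) {
      dA <- metabolic_rate(tr$final_A, tr$final_F, p)
      dF <- behavior_rate(behavior_preset("B4"), tr$final_A, tr$final_F,
                          p = p)
      expect_lt(abs(dA), 1e-5)
      expect_lt(abs(dF), 1e-5)
    } else if (tr$outcome == "survived") {
      expect_gte(max(tr$states$time), 60 - 1e-9)
    }
  }
})
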