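#' Rate constants and death boundaries of the autocatalytic metabolism
#'
#' The metabolism is a single autocatalytic species A produced from an
#' environmental resource F by the mass-action scheme 2A + F <-> 3A, with
#' first-order decay of A. Its intrinsic dynamics are
#' \deqn{dA/dt = k_f F A^2 - k_b A^3 - k_d A}
#' The model cell is dead when A falls to `A_death_low` (metabolic
#' collapse) or rises to `A_death_high` (osmotic crisis: the metabolism has
#' grown so large that the cell bursts). Both boundaries are closed sets:
#' contact counts as death.
#'
#' @param k_forward forward (autocatalytic) rate constant,
#'   concentration^-2 time^-1. Must be > 0.
#' @param k_backward backward rate constant, concentration^-2 time^-1.
#'   Must be > 0.
#' @param k_decay first-order degradation rate of A, time^-1. Must be > 0.
#' @param A_death_low lower death boundary on A (concentration),
#'   0 <= A_death_low < A_death_high.
#' @param A_death_high upper ("osmotic crisis") death boundary on A.
#' @return An object of class `metabolism_params`.
#' @seealso [calibrate_default_params()] for the package's frozen preset,
#'   [equilibria()], [bifurcation_point()], [classify_state()].
#' @examples
#' p <- metabolism_params()
#' bifurcation_point(p)
#' @export
metabolism_params <- function(k_forward = 1.0, k_backward = 0.25,
                              k_decay = 1.0, A_death_low = 0.1,
                              A_death_high = 8.0) {
  stopifnot(is.numeric(k_forward), is.numeric(k_backward),
            is.numeric(k_decay), is.numeric(A_death_low),
            is.numeric(A_death_high))
  vals <- c(k_forward, k_backward, k_decay, A_death_low, A_death_high)
  if (any(!is.finite(vals))) {
    stop("all metabolism parameters must be finite", call. = FALSE)
  }
  if (k_forward <= 0 || k_backward <= 0 || k_decay <= 0) {
    stop("rate constants must be strictly positive", call. = FALSE)
  }
  if (A_death_low < 0 || A_death_low >= A_death_high) {
    stop("need 0 <= A_death_low < A_death_high", call. = FALSE)
  }
  structure(list(k_forward = k_forward, k_backward = k_backward,
                 k_decay = k_decay, A_death_low = A_death_low,
                 A_death_high = A_death_high),
            class = "metabolism_params")
}

#' @export
print.metabolism_params <- function(x, ...) {
  cat("Autocatalytic metabolism parameters\n")
  cat(sprintf("  k_forward = %g, k_backward = %g, k_decay = %g\n",
              x$k_forward, x$k_backward, x$k_decay))
  cat(sprintf("  death boundaries: A <= %g (collapse), A >= %g (osmotic crisis)\n",
              x$A_death_low, x$A_death_high))
  cat(sprintf("  saddle-node bifurcation at F = %g\n", bifurcation_point(x)))
  invisible(x)
}

#' The package's frozen default metabolism preset
#'
#' Returns the calibrated parameter set used throughout the package's
#' experiments. The preset was fixed once, against three qualitative
#' requirements: (i) the bifurcation diagram has a dead branch at A = 0, a
#' saddle-node bifurcation at a resource level strictly inside the
#' explorable window F in \[0, 4\], and stable/unstable branches between
#' the two death lines; (ii) the standard controller parameter ranges
#' (targets theta_A in \[0, 8\], theta_F in \[0, 4\]) span the viable
#' branch and the bistable resource window for this preset; and (iii) the
#' four controllers' survival ordering on the reference survivability grid
#' is reproduced. The preset is pure constants and therefore bit-stable.
#'
#' @return A `metabolism_params` object with k_forward = 1,
#'   k_backward = 0.25, k_decay = 1, A_death_low = 0.1, A_death_high = 8
#'   (bifurcation at F = 1).
#' @export
calibrate_default_params <- function() {
  metabolism_params(k_forward = 1.0, k_backward = 0.25, k_decay = 1.0,
                    A_death_low = 0.1, A_death_high = 8.0)
}

check_state <- function(A, F) {
  if (any(!is.finite(A)) || any(!is.finite(F))) {
    stop("state must be finite", call. = FALSE)
  }
  if (any(A < 0) || any(F < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
}

#' Intrinsic rate of change of the metabolite concentration
#'
#' Evaluates dA/dt = k_f F A^2 - k_b A^3 - k_d A, the intrinsic metabolic
#' dynamics at fixed resource level. Vectorized over `A` and `F`.
#'
#' @param A metabolite concentration(s), >= 0.
#' @param F resource concentration(s), >= 0.
#' @param p a [metabolism_params()] object.
#' @return dA/dt (concentration per time), same length as the recycled
#'   inputs.
#' @examples
#' p <- calibrate_default_params()
#' metabolic_rate(2, 1.5, p)
#' @export
metabolic_rate <- function(A, F, p = calibrate_default_params()) {
  stopifnot(inherits(p, "metabolism_params"))
  check_state(A, F)
  p$k_forward * F * A^2 - p$k_backward * A^3 - p$k_decay * A
}

#' Equilibria of the metabolism at fixed resource concentration
#'
#' A = 0 (the dead state) is always an equilibrium. The positive equilibria
#' are the real roots of the quadratic factor
#' k_b A^2 - k_f F A + k_d = 0: below the saddle-node bifurcation there are
#' none; above it there is an unstable root (the separatrix between decay
#' to death and autocatalytic growth) and a stable viable root, which
#' coincide exactly at the bifurcation.
#'
#' @param F resource concentration (scalar, >= 0).
#' @param p a [metabolism_params()] object.
#' @return An object of class `equilibrium_set`: a list with `dead_root`
#'   (always 0), `unstable_root` and `stable_root` (`NA` below the
#'   bifurcation).
#' @examples
#' equilibria(2, calibrate_default_params())
#' @export
equilibria <- function(F, p = calibrate_default_params()) {
  stopifnot(inherits(p, "metabolism_params"), length(F) == 1L)
  check_state(0, F)
  disc <- (p$k_forward * F)^2 - 4 * p$k_backward * p$k_decay
  if (F > 0 && disc >= 0) {
    sq <- sqrt(disc)
    u <- (p$k_forward * F - sq) / (2 * p$k_backward)
    s <- (p$k_forward * F + sq) / (2 * p$k_backward)
  } else {
    u <- NA_real_
    s <- NA_real_
  }
  structure(list(dead_root = 0, unstable_root = u, stable_root = s),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  if (is.na(x$stable_root)) {
    cat("Equilibria: dead state A = 0 only (below bifurcation)\n")
  } else {
    cat(sprintf(
      "Equilibria: A = 0 (dead), %.6g (unstable), %.6g (stable viable)\n",
      x$unstable_root, x$stable_root))
  }
  invisible(x)
}

#' Resource level of the saddle-node bifurcation
#'
#' Closed form F_bif = 2 sqrt(k_b k_d) / k_f: the resource concentration at
#' which the stable viable branch and the unstable branch are born. For
#' F < F_bif the dead state A = 0 is the only equilibrium; for F > F_bif
#' the system is bistable.
#'
#' @param p a [metabolism_params()] object.
#' @return The bifurcation resource concentration (scalar).
#' @examples
#' bifurcation_point(metabolism_params(1, 1, 1)) # == 2
#' @export
bifurcation_point <- function(p = calibrate_default_params()) {
  stopifnot(inherits(p, "metabolism_params"))
  2 * sqrt(p$k_backward * p$k_decay) / p$k_forward
}

#' Classify a state as viable, precarious, or dead
#'
#' Death is immediate classification: `dead_low` when A <= A_death_low and
#' `dead_high` when A >= A_death_high. A living state is `viable` when,
#' holding F fixed, the intrinsic dynamics carry A to the stable viable
#' equilibrium without touching either death boundary; it is `precarious`
#' when survival requires the resource level to be changed by behavior
#' (the trajectory at fixed F would end in a death state). The
#' classification is analytic, from the factored cubic: a living state is
#' viable iff the stable root exists, lies strictly between the death
#' boundaries, and A lies strictly above the unstable root and strictly
#' below the upper death boundary.
#'
#' Vectorized over `A` and `F`.
#'
#' @param A metabolite concentration(s).
#' @param F resource concentration(s).
#' @param p a [metabolism_params()] object.
#' @return A character vector with elements in
#'   `c("viable", "precarious", "dead_low", "dead_high")`.
#' @examples
#' p <- calibrate_default_params()
#' classify_state(c(0, 3, 0.5, 7.9), c(2, 2, 0.5, 4), p)
#' @export
classify_state <- function(A, F, p = calibrate_default_params()) {
  stopifnot(inherits(p, "metabolism_params"))
  check_state(A, F)
  n <- max(length(A), length(F))
  A <- rep_len(A, n)
  F <- rep_len(F, n)
  disc <- (p$k_forward * F)^2 - 4 * p$k_backward * p$k_decay
  has_roots <- F > 0 & disc >= 0
  sq <- sqrt(pmax(disc, 0))
  u <- (p$k_forward * F - sq) / (2 * p$k_backward)
  s <- (p$k_forward * F + sq) / (2 * p$k_backward)
  lab <- rep("precarious", n)
  viable <- has_roots &
    s > p$A_death_low & s < p$A_death_high &
    A > u & A < p$A_death_high
  lab[viable] <- "viable"
  lab[A <= p$A_death_low] <- "dead_low"
  lab[A >= p$A_death_high] <- "dead_high"
  lab
}

#' Scan the bifurcation diagram over a range of resource levels
#'
#' Tabulates the equilibrium branches (the bold and dashed curves of the
#' bifurcation diagram) over a grid of resource concentrations, suitable
#' for CSV export or plotting.
#'
#' @param p a [metabolism_params()] object.
#' @param F_range length-2 numeric, resource window to scan.
#' @param n number of grid points.
#' @return A data.frame with columns `F`, `dead_root`, `unstable_root`,
#'   `stable_root` (`NA` below the bifurcation).
#' @export
bifurcation_scan <- function(p = calibrate_default_params(),
                             F_range = c(0, 4), n = 201) {
  stopifnot(length(F_range) == 2L, F_range[1] < F_range[2], n >= 2)
  Fs <- seq(F_range[1], F_range[2], length.out = n)
  rows <- lapply(Fs, function(f) {
    e <- equilibria(f, p)
    data.frame(F = f, dead_root = e$dead_root,
               unstable_root = e$unstable_root,
               stable_root = e$stable_root)
  })
  do.call(rbind, rows)
}
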