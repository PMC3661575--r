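#' Survival-based fitness of a behavior
#'
#' A behavior is scored on a lattice of initial conditions by
#' `Fitness = S + V`: `S` is the proportion of the lattice simulations
#' that are survived, and `V` is the normalized mean closeness of the
#' final metabolite concentration to `A_mid`, the midpoint between the two
#' death boundaries. Per cell, the closeness is
#' `max(0, 1 - |final_A - A_mid| / (A_death_high - A_mid))`, so it is 1
#' exactly at the midpoint and falls linearly to 0 at (or beyond) either
#' boundary; dead cells contribute 0. Both terms lie in \[0, 1\], so the
#' total lies in \[0, 2\].
#'
#' @param behavior a [behavior_spec()].
#' @param p a [metabolism_params()] object.
#' @param grid an [initial_grid()] of initial conditions (the fitness
#'   lattice; 21 x 21 by default).
#' @param cfg an [integrator_config()].
#' @return An object of class `fitness_score`: list with `S`, `V`,
#'   `total = S + V`.
#' @examples
#' fitness(behavior_preset("B1"),
#'         grid = initial_grid(resolution = 5),
#'         cfg = integrator_config(dt = 0.02, t_end = 20))
#' @export
fitness <- function(behavior, p = calibrate_default_params(),
                    grid = initial_grid(A_range = c(0, p$A_death_high),
                                        resolution = 21L),
                    cfg = integrator_config(dt = 0.01, t_end = 50,
                                            steady_tol = 1e-4)) {
  g <- survivability_map(behavior, p, grid, cfg)
  score_fitness(g, p)
}

score_fitness <- function(g, p) {
  A_mid <- (p$A_death_low + p$A_death_high) / 2
  half <- p$A_death_high - A_mid
  surv <- g$cells$outcome == "survived"
  S <- mean(surv)
  closeness <- pmax(0, 1 - abs(g$cells$final_A - A_mid) / half)
  closeness[!surv] <- 0
  V <- mean(closeness)
  structure(list(S = S, V = V, total = S + V), class = "fitness_score")
}

#' @export
print.fitness_score <- function(x, ...) {
  cat(sprintf("Fitness: S = %.4f, V = %.4f, total = %.4f\n",
              x$S, x$V, x$total))
  invisible(x)
}

#' Build a fitness closure over a controller's parameter vector
#'
#' Returns `function(par)` mapping a numeric parameter vector (in the
#' controller's canonical order, see [behavior_param_ranges()]) to the
#' total fitness. Used by both [lattice_search()] and [microbial_ga()], so
#' the two search routes are scored identically.
#'
#' @inheritParams fitness
#' @param kind controller kind (`"B1"` .. `"B4"` or 1:4).
#' @param r_max maximum actuation rate.
#' @return A function `par -> total fitness` (deterministic).
#' @export
make_fitness_fn <- function(kind, p = calibrate_default_params(),
                            grid = initial_grid(A_range = c(0, p$A_death_high),
                                                resolution = 11L),
                            cfg = integrator_config(dt = 0.02, t_end = 50,
                                                    steady_tol = 1e-4),
                            r_max = 1.0) {
  if (is.numeric(kind)) kind <- paste0("B", kind)
  fields <- behavior_param_names(kind)
  force(p); force(grid); force(cfg); force(r_max)
  function(par) {
    b <- behavior_spec(kind, as.list(stats::setNames(par, fields)), r_max)
    fitness(b, p, grid, cfg)$total
  }
}

#' Exhaustive lattice search of a two-parameter controller plane
#'
#' Evaluates the fitness at every node of a rectangular lattice over the
#' controller's two allowed parameter ranges and returns the best node
#' (ties broken by first encounter in row-major order: the first parameter
#' indexes rows, the second varies within a row) together with the full
#' fitness surface.
#'
#' @param kind one of `"B1"`, `"B2"`, `"B3"` (two-parameter controllers).
#' @param resolution lattice points per parameter axis.
#' @inheritParams make_fitness_fn
#' @return An object of class `lattice_search_result`: list with `best`
#'   (named parameter vector), `best_fitness`, and `surface` (data.frame
#'   of both parameters and `fitness`).
#' @export
lattice_search <- function(kind, resolution = 101L,
                           p = calibrate_default_params(),
                           grid = initial_grid(A_range = c(0, p$A_death_high),
                                               resolution = 11L),
                           cfg = integrator_config(dt = 0.02, t_end = 50,
                                                   steady_tol = 1e-4),
                           r_max = 1.0) {
  if (is.numeric(kind)) kind <- paste0("B", kind)
  kind <- match.arg(kind, c("B1", "B2", "B3"))
  stopifnot(resolution >= 2)
  rng <- behavior_param_ranges(kind)
  v1 <- seq(rng[1, "lo"], rng[1, "hi"], length.out = resolution)
  v2 <- seq(rng[2, "lo"], rng[2, "hi"], length.out = resolution)
  # row-major: first parameter indexes rows, second varies fastest
  nodes <- expand.grid(p2 = v2, p1 = v1, KEEP.OUT.ATTRS = FALSE)
  fn <- make_fitness_fn(kind, p, grid, cfg, r_max)
  fit <- vapply(seq_len(nrow(nodes)),
                function(i) fn(c(nodes$p1[i], nodes$p2[i])), numeric(1))
  best <- which.max(fit)  # first encounter wins ties
  surface <- data.frame(nodes$p1, nodes$p2, fitness = fit)
  names(surface)[1:2] <- rownames(rng)
  structure(list(
    kind = kind,
    best = stats::setNames(c(nodes$p1[best], nodes$p2[best]), rownames(rng)),
    best_fitness = fit[best], surface = surface,
    resolution = resolution
  ), class = "lattice_search_result")
}

#' @export
print.lattice_search_result <- function(x, ...) {
  cat(sprintf("Lattice search (%s), %d x %d nodes\n", x$kind,
              x$resolution, x$resolution))
  cat(sprintf("  best: %s (fitness %.4f)\n",
              paste(sprintf("%s = %g", names(x$best), x$best),
                    collapse = ", "), x$best_fitness))
  invisible(x)
}

#' Microbial genetic algorithm
#'
#' Steady-state evolutionary search: a random population of genotypes
#' (parameter vectors, uniform within their allowed ranges) is improved by
#' repeated tournaments. Each tournament draws two distinct individuals at
#' random and compares their fitness; the loser's genes are moved toward
#' the winner's by the recombination fraction and then mutated with
#' Gaussian noise whose standard deviation is one percent of the gene's
#' allowed range (by default). Mutated values falling outside the range
#' wrap around into it via modular arithmetic. The winner is never
#' modified, so the best fitness in the population never decreases.
#'
#' @param fitness_fn deterministic function `par -> scalar fitness`.
#' @param ranges 2-column matrix (lo, hi), one row per gene; e.g.
#'   [behavior_param_ranges()].
#' @param pop_size population size (>= 2).
#' @param n_tournaments number of tournaments.
#' @param recomb_frac fraction by which loser genes move toward the
#'   winner's, in (0, 1\].
#' @param mut_sd_frac mutation standard deviation as a fraction of each
#'   gene's range (default 0.01).
#' @param seed integer seed; the run is bit-reproducible from it.
#' @param init_pop optional initial population matrix (`pop_size` rows,
#'   one column per gene, all values inside the ranges); random uniform
#'   when `NULL`.
#' @return An object of class `ga_result`: list with `best` (named
#'   parameter vector), `best_fitness`, `trace` (best-so-far fitness after
#'   each tournament), `population`, `fitness` (final population scores).
#' @examples
#' fn <- function(par) -sum((par - 1)^2)
#' rng <- cbind(lo = c(0, 0), hi = c(4, 4))
#' microbial_ga(fn, rng, pop_size = 10, n_tournaments = 50, seed = 1)$best
#' @export
microbial_ga <- function(fitness_fn, ranges, pop_size = 40L,
                         n_tournaments = 2000L, recomb_frac = 0.5,
                         mut_sd_frac = 0.01, seed = 1L, init_pop = NULL) {
  stopifnot(is.function(fitness_fn), is.matrix(ranges), ncol(ranges) == 2,
            pop_size >= 2, n_tournaments >= 0,
            recomb_frac > 0, recomb_frac <= 1, mut_sd_frac >= 0)
  lo <- ranges[, 1]
  hi <- ranges[, 2]
  stopifnot(all(hi > lo))
  width <- hi - lo
  ng <- nrow(ranges)
  set.seed(seed)
  if (is.null(init_pop)) {
    pop <- matrix(stats::runif(pop_size * ng, rep(lo, each = pop_size),
                               rep(hi, each = pop_size)),
                  nrow = pop_size, ncol = ng)
  } else {
    stopifnot(is.matrix(init_pop), nrow(init_pop) == pop_size,
              ncol(init_pop) == ng)
    pop <- init_pop
  }
  eval_one <- function(g) {
    f <- fitness_fn(g)
    if (!is.finite(f)) {
      stop("non-finite fitness for genotype: ",
           paste(signif(g, 6), collapse = ", "), call. = FALSE)
    }
    f
  }
  fit <- apply(pop, 1, eval_one)
  trace <- numeric(n_tournaments)
  best_so_far <- max(fit)
  for (t in seq_len(n_tournaments)) {
    pair <- sample.int(pop_size, 2L)
    if (fit[pair[1]] >= fit[pair[2]]) {
      win <- pair[1]; lose <- pair[2]
    } else {
      win <- pair[2]; lose <- pair[1]
    }
    g <- pop[lose, ] + recomb_frac * (pop[win, ] - pop[lose, ])
    g <- g + stats::rnorm(ng, 0, mut_sd_frac * width)
    out <- g < lo | g > hi
    g[out] <- lo[out] + (g[out] - lo[out]) %% width[out]
    pop[lose, ] <- g
    fit[lose] <- eval_one(g)
    best_so_far <- max(best_so_far, fit[lose])
    trace[t] <- best_so_far
  }
  best <- which.max(fit)
  rn <- rownames(ranges)
  structure(list(
    best = stats::setNames(pop[best, ], rn),
    best_fitness = fit[best], trace = trace,
    population = pop, fitness = fit,
    config = list(pop_size = pop_size, n_tournaments = n_tournaments,
                  recomb_frac = recomb_frac, mut_sd_frac = mut_sd_frac,
                  seed = seed)
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("Microbial GA: %d genotypes, %d tournaments (seed %d)\n",
              x$config$pop_size, x$config$n_tournaments, x$config$seed))
  nm <- names(x$best)
  lab <- if (is.null(nm)) signif(x$best, 5) else
    sprintf("%s = %g", nm, signif(x$best, 5))
  cat(sprintf("  best: %s (fitness %.4f)\n",
              paste(lab, collapse = ", "), x$best_fitness))
  invisible(x)
}

#' Evolve a controller's parameters with the microbial GA
#'
#' Convenience wrapper tying [microbial_ga()] to a controller's canonical
#' parameter ranges and the shared fitness closure.
#'
#' @inheritParams make_fitness_fn
#' @inheritParams microbial_ga
#' @return A `ga_result`; `best` is named by the controller's parameters
#'   and can be passed to [behavior_spec()] via `as.list()`.
#' @export
evolve_behavior <- function(kind = "B4", p = calibrate_default_params(),
                            grid = initial_grid(A_range = c(0, p$A_death_high),
                                                resolution = 11L),
                            cfg = integrator_config(dt = 0.02, t_end = 50,
                                                    steady_tol = 1e-4),
                            r_max = 1.0, pop_size = 40L,
                            n_tournaments = 2000L, recomb_frac = 0.5,
                            mut_sd_frac = 0.01, seed = 1L) {
  if (is.numeric(kind)) kind <- paste0("B", kind)
  fn <- make_fitness_fn(kind, p, grid, cfg, r_max)
  res <- microbial_ga(fn, behavior_param_ranges(kind), pop_size,
                      n_tournaments, recomb_frac, mut_sd_frac, seed)
  res$kind <- kind
  res
}
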