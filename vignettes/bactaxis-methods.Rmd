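---
title: "Metabolism-coupled behavior: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolism-coupled behavior: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactaxis)
```

## The metabolism

`bactaxis` models the cell's metabolism as a single autocatalytic
species. The mass-action scheme `2A + F ⇌ 3A`, plus first-order decay
`A → ∅`, gives

$$\frac{dA}{dt} = k_f F A^2 - k_b A^3 - k_d A.$$

This is the lowest-order mass-action law with the qualitative structure
the model needs: a stable dead state at $A = 0$, a saddle-node
bifurcation in the resource level $F$, and — above the bifurcation — a
stable "viable" branch separated from death by an unstable branch. The
positive equilibria are the roots of the quadratic factor
$k_b A^2 - k_f F A + k_d$, so everything about the bifurcation structure
is available in closed form; `equilibria()` and `bifurcation_point()`
return these directly, and the test suite checks them against numeric
root-finding on `metabolic_rate()`.

Two assumptions simplify the coupling:

* **The environment is a buffered reservoir.** Metabolic consumption of
  `F` is not fed back; the behavior ODE (or, spatially, the agent's
  position) is the sole driver of `F`. This keeps the non-spatial system
  two-dimensional and the analysis exact.
* **Concentrations are clamped at zero** during integration, because
  they are concentrations.

Death is part of the model, not a numerical artifact. The cell dies of
metabolic collapse at `A_death_low` and of "osmotic crisis" — a
metabolism grown too large for the cell — at `A_death_high`. Both
boundaries are *closed*: exact contact counts as death. A strictly
positive lower threshold (rather than the asymptotic state $A = 0$)
makes death by decay reachable in finite time.

`classify_state()` labels each living state *viable* (the fixed-$F$ flow
reaches the stable branch without touching a boundary) or *precarious*
(survival requires behavior to change `F`). The label is computed
analytically from the factored cubic and is verified cell-by-cell
against brute-force fixed-$F$ integration, excluding a thin
($10^{-3}$-wide) band around the separatrix where any finite-precision
method is undecidable.

### The default preset

`calibrate_default_params()` freezes `k_f = 1`, `k_b = 0.25`,
`k_d = 1`, `A_death_low = 0.1`, `A_death_high = 8` (all concentrations
and times in model units). The preset was chosen once, against three
qualitative requirements, and not revisited:

1. the bifurcation ($F_{bif} = 1$) lies strictly inside the explorable
   resource window $F \in [0, 4]$, so both monostable and bistable
   regimes are reachable;
2. the standard controller parameter ranges make sense for it — the
   resource targets $\theta_F \in [0, 4]$ straddle the bifurcation and
   the metabolite targets $\theta_A \in [0, 8]$ span the viable branch
   (which runs from $A = 2$ at the fold to the osmotic boundary near
   $F \approx 2.13$);
3. the survival ordering of the four published controllers on the
   reference lattice (hybrid > rate-of-change > resource homeostat >
   metabolite homeostat) is reproduced.

## The controllers

All four behaviors share one actuator: the cell can raise or lower the
local resource concentration at up to `r_max` (default 1). Each maps its
sensed quantity through a saturating response
`r_max · tanh(gain · (target − sensed))`. The bounded form follows from
the model's premise of a maximum actuation rate; the gain is a
sensitivity (slope at the target), which is how the parameters
`k_F, k_A, k_D` behave across their `[0, 10]` ranges.

The hybrid controller blends a resource-homeostat branch `B_F` and a
rate-of-change branch `B_D` through a logistic switch in `A`:
$\sigma = 1/(1+e^{-k_r (A - k_\sigma)})$, output
$\sigma B_F + (1-\sigma) B_D$. Of the two switch parameters, `k_sigma`
is assigned the role of the *location* (the metabolite level at which
both branches are equally influential) and `k_r` the *steepness*. The
assignment follows the allowed ranges: `k_sigma`'s range `[0..4]` matches
the mid-range of the `A` domain, while `k_r`'s `[0..10]` matches the
other gains. Both are plain config fields, so the opposite reading costs
one line.

The rate-of-change input `dA/dt` is the analytic `metabolic_rate()` at
the current state — an ideal, lag-free sensor. Sensing lags and receptor
kinetics are deliberately out of scope.

## Integration

The coupled system is integrated with a fixed-step classical RK4 scheme
(compiled); a boundary crossing is detected each step and its time
localized by linear interpolation within the crossing step, after which
the state is frozen (death is absorbing). A fixed step was preferred
over an adaptive pair because every experiment in the package — maps,
fitness lattices, GA runs — depends on bit-reproducibility, and the
event time then converges cleanly at $O(dt)$; the suite cross-checks
trajectories and event times against `deSolve::lsodar` with root
functions. A trajectory also stops early once both $|dA/dt|$ and
$|dF/dt|$ fall below `steady_tol`, i.e. once the system has visibly
come to rest.

Step sizes are matched to the job (the package's own accuracy/cost
choices): `dt = 10^{-3}` for single trajectories and the spatial model,
`dt = 10^{-2}` with `t_end = 100`, `steady_tol = 10^{-6}` for the
51×51 survivability maps, and `dt = 0.02`, `t_end = 50`,
`steady_tol = 10^{-4}` for the optimization runs, where each fitness
evaluation is itself an 11×11 lattice of simulations. Refining any of
these changes survival proportions by well under the margins the
package's comparative claims rest on (the map convergence test halves
`dt` and checks the death time moves by less than the coarser step).

Tie-breaks and degenerate inputs: boundary contact counts as death
(closed death set, so outcomes are well defined); an initial condition
on a boundary dies at $t = 0$; `F = 0` is a valid resource level (the
quadratic then has no roots and every living state is precarious);
negative or non-finite states are rejected at the API boundary.

## Fitness and the two search routes

A controller's fitness on a lattice of initial conditions is
$S + V$: the survived proportion plus the normalized mean closeness of
the final metabolite level to $A_{mid} = (A_{low} + A_{high})/2$, the
midpoint between the dead states. Per cell the closeness is
$\max(0,\, 1 - |A(t_{end}) - A_{mid}| / (A_{high} - A_{mid}))$, with
dead cells scoring 0 — a piecewise-linear normalization that is 1
exactly at the midpoint, 0 at or beyond either boundary, and keeps both
terms on $[0, 1]$ so the total is comparable across controllers.

The two-parameter controllers are optimized by exhaustive lattice
sampling of their parameter planes (101×101 nodes over the allowed
ranges; ties broken by first encounter in row-major order). The
six-parameter hybrid uses the microbial genetic algorithm: random
pairwise tournaments, the loser pulled halfway toward the winner
(recombination fraction 0.5) and mutated with Gaussian noise of sd 1% of
each gene's range, out-of-range values wrapping modularly into range
(values inside the range are never remapped, so the range edges are not
artificially absorbing). Population 40 and 2000 tournaments are
conventional microbial-GA sizes; they converge on the 2-D planes to
within 1% of the exhaustive optimum, which the suite asserts by running
both routes against the *same* fitness closure. Because the winner of a
tournament is never modified, the best-so-far fitness trace is
non-decreasing — a structural property the tests also check.

## The spatial population model

The spatial variant re-expresses the actuator as chemotactic motion:
1000 agents live on $x \in [0, 1]$ under a fixed monotone resource
gradient (linear from $F = 0$ to $F = 4$ by default; a logistic
alternative is provided). Provided it is alive, an agent moves one step
$\pm v\,dt$ per tick — up-gradient when its controller output plus its
fixed error bias $\epsilon$ is non-negative (zero counts as up), else
down-gradient — is relocated onto a wall if it stepped past one, and
updates `A` by one RK4 substep of the metabolism at the local resource
level. Dead agents are frozen.

The agent speed `v = 0.25` is fixed by a rate-matching argument: the
maximum resource change an agent can induce along its path is
$v \cdot (F_{hi} - F_{lo})/(x_{max} - x_{min})$, and `v = 0.25` makes
this equal to the abstract actuator's `r_max = 1`, so the spatial and
non-spatial analyses are dynamically comparable. Initial positions are
flat between the walls, initial metabolite levels flat over
`[0.1, 8]` (the living span of the abstract maps' `A` window), and
$\epsilon \sim N(0, 0.05\,r_{max})$ in the biased runs. Every per-agent
draw comes from an agent-indexed substream of the master seed, so runs
are bit-reproducible and the first $n$ agents of a larger population
are unchanged — the property the determinism tests exercise.

## What the simulations do and do not show

Everything in this package is generated by the model itself; there is no
external data. The experiments emulate the *logic* of
metabolism-coupled behavior — bounded actuation, bistability, death at
both extremes, noisy per-agent biases — not any measured property of a
real organism. In particular the model has no run-and-tumble
stochasticity, no receptor adaptation or signal-transduction kinetics,
no resource depletion or agent–agent interaction, and one metabolite
where a real metabolism has thousands. Passing tests therefore show
that the *mechanisms* behave as designed and that the comparative
claims hold for the calibrated preset; they say nothing quantitative
about real chemotaxing bacteria.

Two results deserve an honest caveat. First, the comparative survival
claims are preset-relative: with other rate constants the margins
between controllers shift, though the structural point — that
single-channel controllers are blind to one dimension of the situation
and fail in conditions the hybrid survives — is robust. Second, on the
abstract lattice the hybrid strictly beats the rate-of-change
controller, but in the spatial model the two are within about two
percentage points of each other (with the rate-of-change controller
slightly ahead in the bias-free runs, and the hybrid losing *less*
survival when the error bias is switched on). The spatial model is
therefore asserted to reproduce the abstract *pattern* — both
metabolism-rate-informed controllers beat both simple homeostats, and
the hybrid is the more bias-robust of the top two — rather than the
exact abstract ranking.

## Run-time problem sizes

The reference experiments use: 51×51 initial-condition lattices for the
survivability maps; 41×41 state lattices for the viability-classifier
verification; a 21×21 fitness lattice for reporting fitness of the
published presets and an 11×11 lattice inside the optimization loops;
101×101 nodes for the exhaustive parameter searches; and 1000 agents
for 100 time units in the spatial runs. These sizes were chosen so the
full reference suite recomputes in minutes on a single core while
leaving every comparative margin above its discretization noise
(halving the map step leaves the survival proportions unchanged to four
decimals, and doubling the lattice resolution moves them by about one
percentage point — lattice-edge cells — without affecting any ordering).
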