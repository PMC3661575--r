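#' Behavioral controllers of the resource level
#'
#' The model cell regulates its environment through a single actuator that
#' can raise or lower the local resource concentration F at up to a
#' maximum rate `r_max`. Each controller maps a sensed quantity to an
#' actuation dF/dt through a saturating tanh response:
#'
#' * **B1** (metabolism-independent): senses F itself and holds it at a
#'   target, `dF/dt = r_max tanh(k_F (theta_F - F))`.
#' * **B2** (metabolism-based): senses the metabolite concentration A,
#'   `dF/dt = r_max tanh(k_A (theta_A - A))`.
#' * **B3** (metabolism-based, rate-of-change): senses dA/dt,
#'   `dF/dt = r_max tanh(k_D (theta_D - dA/dt))`.
#' * **B4** (switching hybrid): blends a B1-style branch and a B3-style
#'   branch through a sigmoid in A; see [behavior4_rate()].
#'
#' @param kind one of `"B1"`, `"B2"`, `"B3"`, `"B4"` (the integers 1:4 are
#'   accepted).
#' @param params named list of controller parameters; defaults to the
#'   published optimized preset for that controller
#'   (see [table1_presets()]).
#' @param r_max maximum achievable |dF/dt| (concentration per time), > 0.
#' @return An object of class `behavior_spec`.
#' @examples
#' b <- behavior_spec("B1")
#' behavior_rate(b, A = 2, F = 0.5)
#' @export
behavior_spec <- function(kind, params = NULL, r_max = 1.0) {
  if (is.numeric(kind)) kind <- paste0("B", kind)
  kind <- match.arg(kind, c("B1", "B2", "B3", "B4"))
  stopifnot(is.numeric(r_max), length(r_max) == 1L, r_max >= 0)
  fields <- behavior_param_names(kind)
  if (is.null(params)) params <- behavior_preset_params(kind)
  if (!setequal(names(params), fields)) {
    stop(sprintf("params for %s must be exactly: %s", kind,
                 paste(fields, collapse = ", ")), call. = FALSE)
  }
  params <- lapply(params[fields], as.numeric)
  gains <- grep("^k_", fields, value = TRUE)
  if (any(unlist(params[gains]) < 0)) {
    stop("gain parameters must be non-negative", call. = FALSE)
  }
  structure(list(kind = kind, params = params, r_max = r_max),
            class = "behavior_spec")
}

behavior_param_names <- function(kind) {
  switch(kind,
         B1 = c("theta_F", "k_F"),
         B2 = c("theta_A", "k_A"),
         B3 = c("theta_D", "k_D"),
         B4 = c("theta_SF", "k_SF", "theta_SD", "k_SD", "k_sigma", "k_r"))
}

behavior_kind_code <- function(kind) {
  match(kind, c("B1", "B2", "B3", "B4"))
}

#' @export
print.behavior_spec <- function(x, ...) {
  desc <- c(B1 = "metabolism-independent resource homeostat",
            B2 = "metabolism-based metabolite homeostat",
            B3 = "metabolism-based rate-of-change controller",
            B4 = "sigmoidal-switch hybrid")
  cat(sprintf("Behavior %s: %s (r_max = %g)\n",
              sub("^B", "", x$kind), desc[[x$kind]], x$r_max))
  cat(" ", paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                 collapse = ", "), "\n")
  invisible(x)
}

#' @rdname behavior_spec
#' @param F,A,dA_dt sensed quantities (resource concentration, metabolite
#'   concentration, metabolite rate of change).
#' @param theta_F,k_F,theta_A,k_A,theta_D,k_D target and gain of the
#'   respective controller.
#' @export
behavior1_rate <- function(F, theta_F, k_F, r_max = 1.0) {
  r_max * tanh(k_F * (theta_F - F))
}

#' @rdname behavior_spec
#' @export
behavior2_rate <- function(A, theta_A, k_A, r_max = 1.0) {
  r_max * tanh(k_A * (theta_A - A))
}

#' @rdname behavior_spec
#' @export
behavior3_rate <- function(dA_dt, theta_D, k_D, r_max = 1.0) {
  r_max * tanh(k_D * (theta_D - dA_dt))
}

#' Sigmoidal switch state of the hybrid controller
#'
#' `sigma = 1 / (1 + exp(-k_r (A - k_sigma)))`: the weight of the
#' metabolism-independent (F-sensing) branch in the hybrid controller.
#' `k_sigma` is the metabolite concentration at which the two branches are
#' equally influential (sigma = 0.5) and `k_r` sets the smoothness of the
#' switch. At high A the F-branch dominates; at low A the rate-of-change
#' branch dominates.
#'
#' @param A metabolite concentration.
#' @param k_sigma switch location in A.
#' @param k_r switch steepness (>= 0).
#' @return sigma in (0, 1), strictly increasing in A when k_r > 0.
#' @export
switch_sigma <- function(A, k_sigma, k_r) {
  1 / (1 + exp(-k_r * (A - k_sigma)))
}

#' Actuation of the sigmoidal-switch hybrid controller
#'
#' `dF/dt = sigma B_F + (1 - sigma) B_D` where
#' `B_F = r_max tanh(k_SF (theta_SF - F))` is the metabolism-independent
#' branch, `B_D = r_max tanh(k_SD (theta_SD - dA/dt))` the rate-of-change
#' branch, and `sigma` is [switch_sigma()] evaluated at the current A.
#'
#' @param A,F,dA_dt current state and metabolite rate of change.
#' @param theta_SF,k_SF F-branch target and gain.
#' @param theta_SD,k_SD derivative-branch target and gain.
#' @param k_sigma,k_r switch location and steepness.
#' @param r_max maximum actuation rate.
#' @return dF/dt, bounded by r_max in magnitude.
#' @export
behavior4_rate <- function(A, F, dA_dt, theta_SF, k_SF, theta_SD, k_SD,
                           k_sigma, k_r, r_max = 1.0) {
  sig <- switch_sigma(A, k_sigma, k_r)
  B_F <- r_max * tanh(k_SF * (theta_SF - F))
  B_D <- r_max * tanh(k_SD * (theta_SD - dA_dt))
  sig * B_F + (1 - sig) * B_D
}

#' Evaluate a behavior's actuation at a state
#'
#' Dispatches to the controller named by the spec. `dA_dt`, when needed
#' (B3, B4), defaults to the analytic [metabolic_rate()] at the current
#' state — the controller senses the true instantaneous rate of change.
#'
#' @param behavior a [behavior_spec()].
#' @param A,F current state.
#' @param dA_dt metabolite rate of change; computed from `p` when `NULL`.
#' @param p a [metabolism_params()] object (used only to derive `dA_dt`).
#' @return dF/dt.
#' @export
behavior_rate <- function(behavior, A, F, dA_dt = NULL,
                          p = calibrate_default_params()) {
  stopifnot(inherits(behavior, "behavior_spec"))
  pr <- behavior$params
  r <- behavior$r_max
  if (is.null(dA_dt) && behavior$kind %in% c("B3", "B4")) {
    dA_dt <- metabolic_rate(A, F, p)
  }
  switch(behavior$kind,
         B1 = behavior1_rate(F, pr$theta_F, pr$k_F, r),
         B2 = behavior2_rate(A, pr$theta_A, pr$k_A, r),
         B3 = behavior3_rate(dA_dt, pr$theta_D, pr$k_D, r),
         B4 = behavior4_rate(A, F, dA_dt, pr$theta_SF, pr$k_SF,
                             pr$theta_SD, pr$k_SD, pr$k_sigma, pr$k_r, r))
}
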