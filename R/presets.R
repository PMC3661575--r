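#' Published optimized controller parameters
#'
#' The reference parameter set for the four controllers: for the three
#' two-parameter controllers the optima were identified by exhaustive
#' lattice sampling of their parameter planes, and for the six-parameter
#' switching hybrid by a microbial genetic algorithm (see
#' [microbial_ga()]). Each row records the parameter, its value, the
#' controller it belongs to, the identification method, and the allowed
#' range (the range also bounds mutation wrap-around in the GA).
#'
#' @return A data.frame with columns `parameter`, `value`, `behavior`,
#'   `method`, `range_lo`, `range_hi`.
#' @examples
#' table1_presets()
#' @export
table1_presets <- function() {
  data.frame(
    parameter = c("theta_F", "k_F", "theta_A", "k_A", "theta_D", "k_D",
                  "theta_SF", "k_SF", "theta_SD", "k_SD", "k_sigma", "k_r"),
    value = c(1.12, 9.4, 4.0, 10.0, 0.0, 10.0,
              1.1033, 2.7381, 0.2894, 2.9981, 2.6494, 6.0630),
    behavior = c("B1", "B1", "B2", "B2", "B3", "B3",
                 "B4", "B4", "B4", "B4", "B4", "B4"),
    method = c(rep("Lattice Sampling", 6), rep("Genetic Algorithm", 6)),
    range_lo = c(0, 0, 0, 0, -2, 0, 0, 0, -1, 0, 0, 0),
    range_hi = c(4, 10, 8, 10, 2, 10, 4, 5, 1, 5, 4, 10),
    stringsAsFactors = FALSE
  )
}

behavior_preset_params <- function(kind) {
  tab <- table1_presets()
  tab <- tab[tab$behavior == kind, ]
  as.list(stats::setNames(tab$value, tab$parameter))
}

#' Allowed parameter ranges for a controller
#'
#' @param kind controller kind (`"B1"` .. `"B4"` or 1:4).
#' @return A 2-column matrix (lo, hi) with one row per parameter, in the
#'   controller's canonical parameter order.
#' @export
behavior_param_ranges <- function(kind) {
  if (is.numeric(kind)) kind <- paste0("B", kind)
  tab <- table1_presets()
  tab <- tab[tab$behavior == kind, ]
  m <- cbind(lo = tab$range_lo, hi = tab$range_hi)
  rownames(m) <- tab$parameter
  m
}

#' Construct a behavior spec from the published preset
#'
#' @param kind controller kind (`"B1"` .. `"B4"` or 1:4).
#' @param r_max maximum actuation rate.
#' @return A [behavior_spec()] carrying the optimized parameters.
#' @examples
#' behavior_preset("B4")
#' @export
behavior_preset <- function(kind, r_max = 1.0) {
  if (is.numeric(kind)) kind <- paste0("B", kind)
  behavior_spec(kind, behavior_preset_params(kind), r_max = r_max)
}
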