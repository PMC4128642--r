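#' Specification for a synthetic stopped-flow trace
#'
#' Describes one simulated relaxation: the true permeability, assay
#' temperature, acquisition window and additive Gaussian noise expressed as
#' a fraction of the total signal amplitude.
#'
#' @param pf_true true osmotic water permeability (cm/s), >= 0
#' @param temperature assay temperature (K)
#' @param noise_sd noise SD as a fraction of the trace amplitude
#' @param n_points number of samples (>= 10)
#' @param duration acquisition window (s)
#' @param dead_time initial mixing-artifact segment (s), excluded by the
#'   fitting routines; must be < `duration`
#' @param seed integer seed; `NULL` leaves the RNG state alone
#' @param label strain/condition label carried on the trace
#' @return an object of class `aq_trace_spec`
#' @export
trace_spec <- function(pf_true, temperature = 296.15, noise_sd = 0.02,
                       n_points = 400, duration = 8, dead_time = 0.005,
                       seed = NULL, label = "synthetic") {
  stopifnot(is.finite(pf_true), pf_true >= 0, noise_sd >= 0,
            n_points >= 10, duration > dead_time, dead_time >= 0)
  structure(list(pf_true = pf_true, temperature = temperature,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 duration = duration, dead_time = dead_time,
                 seed = seed, label = label),
            class = "aq_trace_spec")
}

#' Generate a synthetic stopped-flow trace
#'
#' Integrates the osmometer ODE of `model` with the spec's true Pf, maps
#' volume to fluorescence linearly (normalized so that F(0) = 1), and adds
#' i.i.d. Gaussian noise with SD `noise_sd * (F(0) - F_eq)`. Deterministic
#' given `spec$seed`. With `noise_sd = 0` the output equals the ODE + linear
#' map exactly; with `pf_true = 0` the signal is constant.
#'
#' @param spec a [trace_spec()] object
#' @param model an [cell_model()] object
#' @return an [aq_trace()] object
#' @export
gen_trace <- function(spec, model) {
  stopifnot(inherits(spec, "aq_trace_spec"), inherits(model, "aq_cell_model"))
  times <- seq(0, spec$duration, length.out = spec$n_points)
  v <- simulate_volume(model, spec$pf_true, times)
  f <- volume_to_fluorescence(v, 0, 1 / model$v0)
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    amp <- (model$v0 - equilibrium_volume(model)) / model$v0
    if (amp <= 0) amp <- 1   # iso-osmotic edge: scale noise to the signal
    f <- f + stats::rnorm(length(f), 0, spec$noise_sd * amp)
  }
  aq_trace(times, f, temperature = spec$temperature, label = spec$label)
}

#' Generate an Arrhenius temperature series of Pf values
#'
#' Permeability follows the Arrhenius law
#' `Pf(T) = pf_ref * exp(-(ea/R) * (1/T - 1/t_ref))` with multiplicative
#' log-normal noise of scale `noise_sd`.
#'
#' @param pf_ref permeability at the reference temperature (cm/s)
#' @param t_ref reference temperature (K)
#' @param ea activation energy (kcal/mol), >= 0
#' @param temps temperatures (K), each within 273-320 K
#' @param noise_sd scale of the multiplicative log-normal noise
#' @param seed integer seed; `NULL` leaves the RNG state alone
#' @return a data.frame with columns `temperature` and `pf`
#' @export
gen_temperature_series <- function(pf_ref, t_ref = 296.15, ea, temps,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(pf_ref > 0, ea >= 0, noise_sd >= 0)
  if (length(temps) == 0) stop("'temps' must be non-empty")
  if (any(temps < 273 | temps > 320))
    stop("'temps' must lie within 273-320 K")
  pf <- pf_ref * exp(-(ea / R_KCAL) * (1 / temps - 1 / t_ref))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pf <- pf * exp(stats::rnorm(length(pf), 0, noise_sd))
  }
  data.frame(temperature = temps, pf = pf)
}
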