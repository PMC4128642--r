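#' Two-compartment osmometer model of a cell suspension
#'
#' Defines the geometry and osmotic parameters governing osmotically driven
#' cell volume change after rapid mixing in a stopped-flow experiment. The
#' cell is treated as an ideal osmometer with a non-osmotic volume fraction
#' `beta`: only the osmotically active volume `v0 * (1 - beta)` equilibrates
#' with the external medium.
#'
#' Volume follows
#' \deqn{dV/dt = -P_f A V_w (osm_{out} - osm_{in,0} (V_0 - V_b)/(V - V_b))}
#' with \eqn{V_b = \beta V_0}, water molar volume \eqn{V_w = 18} cm3/mol and
#' osmolarities in mol/cm3 internally (molar at this interface).
#'
#' Defaults describe a spherical yeast cell of radius 2.5 um equilibrated in
#' 1.4 M sorbitol and challenged with an equal volume of 2.1 M sorbitol
#' (final external osmolarity 1.75 M).
#'
#' @param radius_um cell radius in micrometres (used when `v0`/`area` are not
#'   given; for a sphere `v0/area = r/3`)
#' @param beta non-osmotic volume fraction of `v0`, in `[0, 1)`
#' @param osm_in initial intracellular osmolarity (mol/L)
#' @param osm_out final extracellular osmolarity after mixing (mol/L)
#' @param vw molar volume of water (cm3/mol)
#' @param v0,area initial cell volume (cm3) and surface area (cm2); override
#'   the spherical geometry when supplied (both or neither)
#' @return an object of class `aq_cell_model`
#' @examples
#' m <- cell_model()
#' equilibrium_volume(m) / m$v0   # fractional final volume
#' @export
cell_model <- function(radius_um = 2.5, beta = 0.5, osm_in = 1.4,
                       osm_out = 1.75, vw = 18, v0 = NULL, area = NULL) {
  if (is.null(v0) != is.null(area))
    stop("supply both 'v0' and 'area', or neither")
  if (is.null(v0)) {
    r <- radius_um * 1e-4                 # cm
    if (!is.finite(r) || r <= 0) stop("'radius_um' must be positive")
    v0 <- 4 / 3 * pi * r^3
    area <- 4 * pi * r^2
  }
  stopifnot(v0 > 0, area > 0, vw > 0, osm_in > 0, osm_out > 0)
  if (!is.finite(beta) || beta < 0 || beta >= 1)
    stop("'beta' must be in [0, 1)")
  structure(list(
    v0 = v0, area = area, beta = beta, vw = vw,
    osm_in0 = osm_in * 1e-3,              # mol/cm3
    osm_out = osm_out * 1e-3
  ), class = "aq_cell_model")
}

#' @export
print.aq_cell_model <- function(x, ...) {
  cat("Cell suspension osmometer model\n")
  cat(sprintf("  v0 = %.3g cm3, area = %.3g cm2 (v0/area = %.3g cm)\n",
              x$v0, x$area, x$v0 / x$area))
  cat(sprintf("  non-osmotic fraction beta = %.2f\n", x$beta))
  cat(sprintf("  osmolarities: %.3g -> %.3g M (shock ratio %.3f)\n",
              x$osm_in0 * 1e3, x$osm_out * 1e3, x$osm_out / x$osm_in0))
  invisible(x)
}

#' Equilibrium (final) cell volume after an osmotic shock
#'
#' Van't Hoff equilibrium of the osmotically active compartment:
#' `V_eq = v_b + (v0 - v_b) * osm_in0 / osm_out`.
#'
#' @param model an [cell_model()] object
#' @return equilibrium volume (cm3)
#' @export
equilibrium_volume <- function(model) {
  vb <- model$beta * model$v0
  vb + (model$v0 - vb) * model$osm_in0 / model$osm_out
}

#' Linearized shrinkage rate constant
#'
#' Rate constant of the volume relaxation linearized about the equilibrium
#' volume: `k = Pf * (A / (v0 (1 - beta))) * vw * osm_out^2 / osm_in0`.
#' This is the small-shock limit of the observable single-exponential rate.
#'
#' @param model an [cell_model()] object
#' @param pf osmotic water permeability (cm/s)
#' @return rate constant (1/s)
#' @export
linearized_rate <- function(model, pf) {
  pf * (model$area / (model$v0 * (1 - model$beta))) *
    model$vw * model$osm_out^2 / model$osm_in0
}

#' Simulate osmotic cell shrinkage
#'
#' Integrates the osmometer ODE (see [cell_model()]) from `V(0) = v0` at the
#' requested times.
#'
#' @param model an [cell_model()] object
#' @param pf osmotic water permeability (cm/s), non-negative
#' @param times numeric vector of times (s), starting at or after 0
#' @return numeric vector of volumes (cm3) at `times`
#' @export
simulate_volume <- function(model, pf, times) {
  stopifnot(is.numeric(pf), length(pf) == 1, is.finite(pf))
  if (pf < 0) stop("'pf' must be non-negative")
  if (length(times) < 1 || any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  vb <- model$beta * model$v0
  w0 <- model$v0 - vb
  deriv <- function(t, y, parms) {
    w <- y[1] - vb
    list(-pf * model$area * model$vw *
           (model$osm_out - model$osm_in0 * w0 / w))
  }
  t_ode <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::ode(c(V = model$v0), t_ode, deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12 * model$v0)
  v <- sol[, "V"]
  if (times[1] > 0) v <- v[-1]
  if (any(!is.finite(v)))
    stop("non-finite volume solution; check 'pf' and model osmolarities")
  if (any(v - vb <= 0))
    stop("osmotic volume collapsed to zero: nonphysical parameters ",
         "(beta, osm_out)")
  unname(v)
}

#' Map cell volume to a fluorescence signal
#'
#' The intracellular fluorophore is quenched upon shrinkage, so fluorescence
#' tracks volume linearly: `F = c0 + c1 * V`. The map is affine and
#' invertible given `(c0, c1)`; the fitted relaxation rate is invariant under
#' it.
#'
#' @param volumes numeric vector of volumes (cm3)
#' @param c0 offset (arbitrary units)
#' @param c1 slope (a.u. per cm3), positive
#' @return fluorescence series (a.u.)
#' @export
volume_to_fluorescence <- function(volumes, c0 = 0, c1 = 1) {
  if (!is.finite(c1) || c1 <= 0) stop("'c1' must be positive")
  c0 + c1 * volumes
}
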