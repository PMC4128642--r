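#' Gas constant in kcal / (mol K)
#' @keywords internal
R_KCAL <- 1.987e-3

#' Arrhenius activation energy of water transport
#'
#' Ordinary least squares of `ln(Pf)` on `1/T`; the activation energy is
#' `Ea = -slope * R` with `R = 1.987e-3` kcal/(mol K). Channel-mediated
#' water flux shows low Ea (< ~6-10 kcal/mol); lipid-diffusion-dominated
#' flux shows high Ea.
#'
#' Duplicate temperatures are collapsed to their mean Pf before the
#' regression; at least 3 distinct temperatures are required.
#'
#' @param series either a data.frame with columns `temperature` (K) and `pf`
#'   (cm/s), or a list of [estimate_pf()] results (their `temperature` and
#'   `pf_mean` are used)
#' @return an object of class `aq_arrhenius` with `ea` (kcal/mol), its
#'   standard error `ea_se`, `intercept` (ln cm/s), `r_squared`, `n_temps`
#'   and the collapsed `data`
#' @examples
#' s <- gen_temperature_series(4.3e-4, 296.15, ea = 14.05,
#'                             temps = c(282.15, 289.15, 296.15, 303.15, 310.15))
#' estimate_ea(s)
#' @export
estimate_ea <- function(series) {
  if (is.list(series) && !is.data.frame(series) &&
      all(vapply(series, inherits, logical(1), "aq_pf"))) {
    series <- data.frame(
      temperature = vapply(series, `[[`, numeric(1), "temperature"),
      pf = vapply(series, `[[`, numeric(1), "pf_mean"))
  }
  stopifnot(is.data.frame(series),
            all(c("temperature", "pf") %in% names(series)))
  if (any(series$pf <= 0)) stop("all Pf values must be positive")
  d <- stats::aggregate(pf ~ temperature, data = series, FUN = mean)
  if (nrow(d) < 3) stop("need at least 3 distinct temperatures")
  d$inv_t <- 1 / d$temperature
  fit <- stats::lm(log(pf) ~ inv_t, data = d)
  sm <- suppressWarnings(summary(fit))  # noiseless series fit perfectly
  slope <- unname(stats::coef(fit)[2])
  structure(list(
    ea = -slope * R_KCAL,
    ea_se = unname(sm$coefficients[2, 2]) * R_KCAL,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    n_temps = nrow(d),
    data = d[c("temperature", "pf")],
    fit = fit
  ), class = "aq_arrhenius")
}

#' @export
print.aq_arrhenius <- function(x, ...) {
  cat(sprintf("Arrhenius fit over %d temperatures (%.1f-%.1f K)\n",
              x$n_temps, min(x$data$temperature), max(x$data$temperature)))
  cat(sprintf("  Ea = %.2f +/- %.2f kcal/mol, r^2 = %.4f\n",
              x$ea, x$ea_se, x$r_squared))
  invisible(x)
}

#' @export
coef.aq_arrhenius <- function(object, ...) {
  c(ea = object$ea, intercept = object$intercept)
}

#' @export
plot.aq_arrhenius <- function(x, ...) {
  graphics::plot(1 / x$data$temperature, log(x$data$pf),
                 xlab = "1/T (1/K)", ylab = "ln Pf (ln cm/s)",
                 pch = 16, ...)
  graphics::abline(x$intercept, -x$ea / R_KCAL, col = "red")
  invisible(x)
}
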