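#' Fit a single exponential to a stopped-flow relaxation
#'
#' Least-squares fit of \eqn{F(t) = baseline + amplitude \cdot e^{-k t}} to a
#' trace, restricted to `t >= dead_time` (the initial mixing artifact is
#' excluded). Starting values come from a log-linear regression of
#' `F - baseline0` over the first 80% of the retained points, with
#' `baseline0` the mean of the last 10%; on non-convergence the fit is
#' restarted once at twice the initial rate.
#'
#' @param trace an [aq_trace()] object
#' @param dead_time seconds excluded from the start of the record
#' @return an object of class `aq_expfit` with components `k` (1/s),
#'   `amplitude`, `baseline`, `rmse`, `n_points`, the retained `times` and
#'   `fluorescence`, `dead_time` and a `no_relaxation` flag
#' @seealso [pf_from_rate()] to convert the rate constant to a permeability
#' @export
fit_single_exponential <- function(trace, dead_time = 0.005) {
  stopifnot(inherits(trace, "aq_trace"), dead_time >= 0)
  keep <- trace$times >= dead_time
  t <- trace$times[keep]
  f <- trace$fluorescence[keep]
  n <- length(t)
  if (n < 8)
    stop("fewer than 8 points remain after dead-time exclusion")

  baseline0 <- mean(f[ceiling(0.9 * n):n])
  d <- f - baseline0
  i80 <- seq_len(ceiling(0.8 * n))
  pos <- i80[d[i80] > 0]
  amp_scale <- max(abs(d))
  if (length(pos) < 3 || amp_scale < 1e-12 * max(abs(f), 1))
    stop(no_relaxation_error(trace$label))
  ll <- stats::lm(log(d[pos]) ~ t[pos])
  k0 <- max(-unname(stats::coef(ll)[2]), 1e-6)
  a0 <- exp(unname(stats::coef(ll)[1]))

  do_fit <- function(kstart) {
    minpack.lm::nlsLM(f ~ b + a * exp(-k * t),
                      start = list(b = baseline0, a = a0, k = kstart),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- tryCatch(do_fit(k0), error = function(e) NULL)
  if (is.null(fit)) fit <- tryCatch(do_fit(2 * k0), error = function(e)
    stop("exponential fit failed to converge (k0 = ", signif(k0, 4),
         ", amplitude0 = ", signif(a0, 4), ")", call. = FALSE))
  cf <- stats::coef(fit)
  k <- unname(cf["k"])
  no_relax <- !is.finite(k) || k <= 0
  if (no_relax)
    warning("no relaxation detected in trace '", trace$label,
            "' (k <= 0 at optimum)", call. = FALSE)
  res <- f - (cf["b"] + cf["a"] * exp(-k * t))
  structure(list(
    k = k,
    amplitude = unname(cf["a"]),
    baseline = unname(cf["b"]),
    rmse = sqrt(mean(res^2)),
    n_points = n,
    times = t,
    fluorescence = f,
    dead_time = dead_time,
    temperature = trace$temperature,
    label = trace$label,
    no_relaxation = no_relax
  ), class = "aq_expfit")
}

no_relaxation_error <- function(label) {
  structure(class = c("aq_no_relaxation", "error", "condition"),
            list(message = paste0("no relaxation detected in trace '",
                                  label, "'"),
                 call = NULL))
}

#' @export
print.aq_expfit <- function(x, ...) {
  cat(sprintf("Single-exponential fit '%s'\n", x$label))
  cat(sprintf("  k = %.5g 1/s, amplitude = %.4g, baseline = %.4g\n",
              x$k, x$amplitude, x$baseline))
  cat(sprintf("  rmse = %.3g over %d points (dead time %.3g s)\n",
              x$rmse, x$n_points, x$dead_time))
  if (x$no_relaxation) cat("  ** no relaxation detected (k <= 0) **\n")
  invisible(x)
}

#' @export
coef.aq_expfit <- function(object, ...) {
  c(k = object$k, amplitude = object$amplitude, baseline = object$baseline)
}

#' @export
predict.aq_expfit <- function(object, times = object$times, ...) {
  object$baseline + object$amplitude * exp(-object$k * times)
}

#' @export
fitted.aq_expfit <- function(object, ...) predict(object)

#' @export
residuals.aq_expfit <- function(object, ...) {
  object$fluorescence - predict(object)
}

#' @export
plot.aq_expfit <- function(x, ...) {
  graphics::plot(x$times, x$fluorescence, pch = 16, cex = 0.4,
                 xlab = "time (s)", ylab = "fluorescence (a.u.)",
                 main = x$label, ...)
  graphics::lines(x$times, predict(x), col = "red", lwd = 2)
  invisible(x)
}
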