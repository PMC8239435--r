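#' Parameters of the two-programme toggle switch
#'
#' Bundles the constants of the toggle-switch dynamical system together with
#' the numerical settings used for trajectory integration and attractor
#' assignment. The defaults (`a = b = k = 1`, `n = 4`, `theta = 0.5`) put the
#' system in its tri-stable regime, with two mirror-symmetric single-programme
#' attractors and one balanced ("ambivalent") attractor on the diagonal.
#'
#' @param a Auto-amplification strength of each programme (unitless, > 0).
#' @param b Cross-inhibition strength (unitless, > 0).
#' @param k First-order decay rate of each programme (1/time, > 0).
#' @param n Hill coefficient of both regulatory terms (integer >= 1).
#' @param theta Hill threshold of both regulatory terms (> 0).
#' @param x_max Upper bound of the phase-portrait window on each axis. The
#'   default 2.2 contains all three attractors of the default parameter set:
#'   at saturation a programme is driven at rate `a + b` and decays at `k`,
#'   so the asymmetric attractors sit near programme level `(a + b)/k = 2`.
#' @param t_max Maximum integration time per trajectory.
#' @param conv_tol Velocity-norm threshold below which a trajectory is
#'   considered converged.
#' @param attract_eps Radius around a stable fixed point within which a
#'   terminal state is assigned to that attractor.
#' @return An object of class `toggle_params` (a validated list).
#' @examples
#' p <- toggle_params()
#' velocity_field(c(0, 0), p)  # (1, 1): pure cross-activation at the origin
#' @export
toggle_params <- function(a = 1, b = 1, k = 1, n = 4, theta = 0.5,
                          x_max = 2.2, t_max = 100,
                          conv_tol = 1e-6, attract_eps = 0.05) {
  p <- list(a = a, b = b, k = k, n = n, theta = theta, x_max = x_max,
            t_max = t_max, conv_tol = conv_tol, attract_eps = attract_eps)
  validate_toggle_params(p)
  structure(p, class = "toggle_params")
}

validate_toggle_params <- function(p) {
  errs <- character()
  for (f in c("a", "b", "k", "theta", "x_max", "t_max", "conv_tol",
              "attract_eps")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      errs <- c(errs, sprintf("'%s' must be a single positive number", f))
  }
  if (!is.numeric(p$n) || length(p$n) != 1L || !is.finite(p$n) ||
      p$n < 1 || p$n != round(p$n))
    errs <- c(errs, "'n' must be an integer >= 1")
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  invisible(p)
}

#' @export
print.toggle_params <- function(x, ...) {
  cat("Toggle-switch parameters\n")
  cat(sprintf("  a = %g, b = %g, k = %g, n = %d, theta = %g\n",
              x$a, x$b, x$k, x$n, x$theta))
  cat(sprintf("  window [0, %g]^2, t_max = %g, conv_tol = %g, attract_eps = %g\n",
              x$x_max, x$t_max, x$conv_tol, x$attract_eps))
  invisible(x)
}

as_toggle_params <- function(p) {
  if (inherits(p, "toggle_params")) return(p)
  if (is.list(p)) return(do.call(toggle_params, p))
  stop("'params' must be a toggle_params object or a named list", call. = FALSE)
}
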