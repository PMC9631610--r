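#' Deterministic GC-content trajectory
#'
#' Closed-form solution of the noise-free GC-content ODE
#' \eqn{dF/dt = a F + b (1 - F)}:
#' \deqn{F(t) = -\frac{b}{a-b} + \Big(F_0 + \frac{b}{a-b}\Big) e^{(a-b)t}.}
#' Under the AT-bias regime \eqn{a - b < 0} the trajectory relaxes
#' exponentially towards the equilibrium GC fraction \eqn{-b/(a-b) =
#' b/(b-a)}. The degenerate case \eqn{a = b} is handled by its analytic
#' limit \eqn{F(t) = F_0 + b t} (the 0/0 singularity is removable).
#'
#' Values are returned unclamped; a warning is emitted if the result
#' leaves (0, 1), since the model statement \eqn{0 < F_t < 1} is a
#' constraint on interpretation, not on the algebra.
#'
#' @param params A [rate_parameters()] object.
#' @param t Non-negative time(s); vectorised.
#' @return Numeric vector of GC fractions, same length as `t`.
#' @examples
#' p <- rate_parameters(a = -2, b = 1, F0 = 0.5)
#' deterministic_gc(p, c(0, 0.5, 1))
#' @export
deterministic_gc <- function(params, t) {
  stopifnot(inherits(params, "rate_parameters"))
  check_times(t)
  out <- gc_mean_closed_form(params$a, params$b, params$F0, t)
  warn_if_outside_unit(out, "deterministic_gc")
  out
}

#' Expected GC content under random rate perturbations
#'
#' The Brownian term of the SDE solution is a (mean-zero) Ito integral, so
#' the expectation equals the deterministic trajectory. For \eqn{F_0 = 0}
#' this is \deqn{E(F_t) = \frac{b}{a-b}\big(e^{(a-b)t} - 1\big),}
#' the curve also used as the SNP GC-content model in
#' [predict_snp_gc()]. For \eqn{a = b} the limit \eqn{E(F_t) = b t}
#' is used.
#'
#' @inheritParams deterministic_gc
#' @return Numeric vector of expected GC fractions.
#' @examples
#' p <- rate_parameters(a = -2, b = 1, F0 = 0, allow_boundary_F0 = TRUE)
#' expected_gc(p, 1)   # (1 - exp(-3)) / 3
#' @export
expected_gc <- function(params, t) {
  stopifnot(inherits(params, "rate_parameters"))
  check_times(t)
  out <- gc_mean_closed_form(params$a, params$b, params$F0, t)
  warn_if_outside_unit(out, "expected_gc")
  out
}

# Shared mean/deterministic closed form with the a = b limit branch.
# |a - b| < ab_tol switches to F0 + b t (removable singularity).
gc_mean_closed_form <- function(a, b, F0, t, ab_tol = 1e-10) {
  d <- a - b
  if (abs(d) < ab_tol) {
    F0 + b * t
  } else {
    -b / d + (F0 + b / d) * exp(d * t)
  }
}

check_times <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative finite time(s).", call. = FALSE)
  }
  invisible(t)
}

warn_if_outside_unit <- function(x, what) {
  if (any(x < 0 | x > 1)) {
    warning(sprintf("%s: value outside (0, 1); the model constraint 0 < F_t < 1 is violated for these parameters/times.",
                    what), call. = FALSE)
  }
  invisible(x)
}

#' Variance of GC content via the Ito isometry
#'
#' The stochastic term of the SDE solution is
#' \eqn{\int_0^t c(s) e^{(a-b)(t-s)} dB_s}; by the Ito isometry its
#' variance is the ordinary integral
#' \deqn{\mathrm{Var}(F_t) = \int_0^t c(s)^2 e^{2(a-b)(t-s)}\, ds,}
#' which for general \eqn{c} has no closed form and is evaluated by
#' adaptive quadrature (absolute tolerance `tol`), falling back to a
#' composite-trapezoid rule on `fallback_nodes` nodes if the adaptive
#' rule fails to converge.
#'
#' @param params A [rate_parameters()] object (only \eqn{a - b} enters).
#' @param sched A [perturbation_schedule()].
#' @param t Time(s) in `[0, sched$domain_end]`; vectorised.
#' @param tol Absolute quadrature tolerance. Default `1e-10`.
#' @param fallback_nodes Trapezoid fallback resolution. Default `1e4`.
#' @return Non-negative variance(s), zero at `t = 0`.
#' @examples
#' p <- rate_parameters(a = -2, b = 1, F0 = 0.5)
#' variance_gc(p, sched_const(0.5), 1)  # 0.25 (1 - e^{-6}) / 6
#' @export
variance_gc <- function(params, sched, t, tol = 1e-10, fallback_nodes = 1e4) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(sched, "perturbation_schedule"))
  check_times(t)
  if (any(t > sched$domain_end + 1e-12)) {
    stop("`t` must lie within the schedule domain [0, T].", call. = FALSE)
  }
  d <- params$a - params$b
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    integrand <- function(s) sched_eval(sched, s)^2 * exp(2 * d * (ti - s))
    val <- tryCatch({
      q <- stats::integrate(integrand, 0, ti, abs.tol = tol,
                            rel.tol = tol, subdivisions = 500L,
                            stop.on.error = TRUE)
      q$value
    }, error = function(e) {
      s <- seq(0, ti, length.out = as.integer(fallback_nodes))
      trapz(s, integrand(s))
    })
    if (!is.finite(val) || val < -tol) {
      stop("variance quadrature failed to converge to a finite non-negative value.",
           call. = FALSE)
    }
    max(val, 0)
  }, numeric(1))
}

# composite trapezoid on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
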