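#' Perturbation schedule c(t)
#'
#' The deterministic, measurable function \eqn{c(t) \ge 0} that scales the
#' Gaussian white-noise perturbation of the mutation rates. In the model
#' the perturbed rates are \eqn{\alpha = a + c(t) W_t} and
#' \eqn{\beta = b + c(t) W_t}; after rearrangement \eqn{c(t)} multiplies
#' the Brownian driver of the SDE. Schedule metadata (constancy,
#' monotonicity, infimum) is probed numerically on a dense grid at
#' construction and consulted by the Girsanov machinery.
#'
#' @param c_fun Vectorised function of time returning non-negative values.
#' @param domain_end End \eqn{T} of the schedule's domain \eqn{[0, T]}.
#' @param n_probe Number of probe points used to derive metadata.
#' @param label Optional human-readable label.
#'
#' @return An object of class `perturbation_schedule`: a callable list with
#'   elements `c_fun`, `domain_end`, `is_constant`, `monotonicity`
#'   (`"increasing"`, `"decreasing"`, or `"none"`), `lower_bound`, `label`.
#' @examples
#' sch <- perturbation_schedule(function(t) 0.5 * sqrt(t), domain_end = 1)
#' sch$monotonicity
#' sched_const(0.5)
#' @seealso [sched_const()], [sched_sqrt()], [sched_linear_decay()],
#'   [sched_quad_decay()]
#' @export
perturbation_schedule <- function(c_fun, domain_end = 1, n_probe = 2048L,
                                  label = NULL) {
  stopifnot(is.function(c_fun))
  if (!is.numeric(domain_end) || length(domain_end) != 1L ||
      !is.finite(domain_end) || domain_end <= 0) {
    stop("`domain_end` must be a positive finite scalar.", call. = FALSE)
  }
  tt <- seq(0, domain_end, length.out = n_probe)
  vv <- c_fun(tt)
  if (length(vv) != length(tt)) {
    vv <- vapply(tt, c_fun, numeric(1))  # non-vectorised c
  }
  if (any(!is.finite(vv))) {
    stop("c(t) must be finite on [0, T].", call. = FALSE)
  }
  if (any(vv < 0)) {
    stop(sprintf("c(t) must be non-negative on [0, T]; c(%.6g) = %.6g < 0.",
                 tt[which(vv < 0)[1L]], min(vv)), call. = FALSE)
  }
  d <- diff(vv)
  tol <- 1e-12 * max(1, max(abs(vv)))
  mono <- if (all(abs(d) <= tol)) {
    "none"  # constant; monotonicity flag not meaningful
  } else if (all(d >= -tol)) {
    "increasing"
  } else if (all(d <= tol)) {
    "decreasing"
  } else {
    "none"
  }
  structure(
    list(c_fun = c_fun,
         domain_end = domain_end,
         is_constant = all(abs(d) <= tol),
         monotonicity = mono,
         lower_bound = min(vv),
         label = label %||% "c(t)"),
    class = "perturbation_schedule")
}

#' @export
print.perturbation_schedule <- function(x, ...) {
  cat(sprintf(
    "<perturbation_schedule>  %s on [0, %g]  (constant: %s, monotonicity: %s, inf c = %g)\n",
    x$label, x$domain_end, x$is_constant, x$monotonicity, x$lower_bound))
  invisible(x)
}

#' Evaluate a perturbation schedule
#'
#' @param sched A [perturbation_schedule()].
#' @param t Numeric vector of times.
#' @return Numeric vector `c(t)`.
#' @export
sched_eval <- function(sched, t) {
  stopifnot(inherits(sched, "perturbation_schedule"))
  v <- sched$c_fun(t)
  if (length(v) != length(t)) v <- vapply(t, sched$c_fun, numeric(1))
  v
}

#' Named perturbation schedules
#'
#' Constructors for the schedule families used throughout:
#' constant \eqn{c(t) = c_0}, square-root growth
#' \eqn{c(t) = \kappa \sqrt{t}}, linear decay \eqn{c(t) = \kappa (T - t)},
#' and quadratic decay \eqn{c(t) = \kappa (T - t)^2}. The three
#' non-constant families, at \eqn{\kappa = 1/2} and \eqn{T = 1}, are the
#' canonical scenarios of growing, shrinking, and rapidly shrinking
#' perturbation pressure.
#'
#' @param c0 Constant level, non-negative.
#' @param kappa Scale coefficient, non-negative.
#' @param t_end Domain end \eqn{T}.
#' @return A [perturbation_schedule()].
#' @examples
#' sched_sqrt(0.5)           # c(t) = (1/2) sqrt(t)
#' sched_linear_decay(0.5)   # c(t) = (1/2) (1 - t)
#' @export
sched_const <- function(c0, t_end = 1) {
  stopifnot(is.numeric(c0), length(c0) == 1L, is.finite(c0), c0 >= 0)
  force(c0)
  perturbation_schedule(function(t) rep_len(c0, length(t)), t_end,
                        label = sprintf("const(%g)", c0))
}

#' @rdname sched_const
#' @export
sched_sqrt <- function(kappa = 0.5, t_end = 1) {
  force(kappa)
  perturbation_schedule(function(t) kappa * sqrt(pmax(t, 0)), t_end,
                        label = sprintf("%g*sqrt(t)", kappa))
}

#' @rdname sched_const
#' @export
sched_linear_decay <- function(kappa = 0.5, t_end = 1) {
  force(kappa); force(t_end)
  perturbation_schedule(function(t) kappa * pmax(t_end - t, 0), t_end,
                        label = sprintf("%g*(T - t)", kappa))
}

#' @rdname sched_const
#' @export
sched_quad_decay <- function(kappa = 0.5, t_end = 1) {
  force(kappa); force(t_end)
  perturbation_schedule(function(t) kappa * pmax(t_end - t, 0)^2, t_end,
                        label = sprintf("%g*(T - t)^2", kappa))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
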