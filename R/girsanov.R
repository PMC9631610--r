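#' Girsanov drift that makes the GC process driftless
#'
#' Under the integrating-factor transform \eqn{Y_t = e^{-(a-b)t} F_t} the
#' SDE becomes \eqn{dY_t = b e^{-(a-b)t} dt + c(t) e^{-(a-b)t} dB_t}. The
#' Girsanov change of measure that removes the drift uses
#' \deqn{u(t) = b / c(t),}
#' which is deterministic (no path dependence) and requires \eqn{c(t) > 0}
#' on the whole grid. Positivity — not monotonicity — is what the algebra
#' needs; a non-monotonic schedule only triggers an advisory warning,
#' reflecting the interpretation of invertible (monotone) schedules in
#' laboratory-evolution settings.
#'
#' @param params A [rate_parameters()] object (only `b` enters).
#' @param sched A [perturbation_schedule()], strictly positive on the grid.
#' @param grid A [time_grid()].
#' @return Numeric vector `u(t)` at the left endpoints
#'   `grid$times[1..n_steps]`.
#' @examples
#' p <- rate_parameters(a = -2, b = 1, F0 = 0.5)
#' girsanov_drift(p, sched_const(0.5), time_grid(1, 4))  # u = 2 throughout
#' @export
girsanov_drift <- function(params, sched, grid) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(sched, "perturbation_schedule"), is_time_grid(grid))
  s_left <- grid$times[-length(grid$times)]
  cv <- sched_eval(sched, s_left)
  if (any(cv <= 0)) {
    bad <- s_left[which(cv <= 0)[1L]]
    stop(sprintf(
      "c(t) must be strictly positive for the Girsanov drift; c(%g) = %g.",
      bad, cv[which(cv <= 0)[1L]]), call. = FALSE)
  }
  if (!sched$is_constant && sched$monotonicity == "none") {
    warning("schedule c(t) is not monotonic; the change of measure is still valid (positivity suffices), but the monotone-schedule interpretation does not apply.",
            call. = FALSE)
  }
  params$b / cv
}

#' Novikov condition diagnostic
#'
#' For a deterministic drift \eqn{u(t)} the Novikov condition
#' \eqn{E[\exp(\frac12 \int_0^T u^2 ds)] < \infty} reduces to finiteness
#' of \eqn{\exp(\frac12 \int_0^T u(s)^2 ds)}, evaluated here by the
#' trapezoid rule on the tabulated drift. Overflow (a divergent integral,
#' e.g. \eqn{u \sim 1/t} near 0) is reported as `Inf`.
#'
#' @param u_values Drift tabulated at the left endpoints of `grid`.
#' @param grid The matching [time_grid()].
#' @return The scalar \eqn{\exp(\frac12 \int u^2 ds)}; `Inf` if the
#'   integral diverges or overflows.
#' @examples
#' g <- time_grid(1, 1000)
#' novikov_check(rep(2, 1000), g)  # exp(2)
#' @export
novikov_check <- function(u_values, grid) {
  stopifnot(is_time_grid(grid), length(u_values) == grid$n_steps)
  if (any(!is.finite(u_values))) {
    stop("non-finite drift values; the Girsanov drift is undefined here.",
         call. = FALSE)
  }
  half_int <- 0.5 * sum(u_values^2) * grid$dt
  exp(half_int)  # overflows to Inf exactly when the condition fails
}

#' Per-path Radon--Nikodym log-weights
#'
#' Computes \eqn{\log M_T = -\sum_i u(s_i)\Delta B_i -
#' \frac12 \sum_i u(s_i)^2 \Delta s} from the same Brownian increments
#' that drove the ensemble. For deterministic \eqn{u} the weights are
#' exactly lognormal with \eqn{E[M_T] = 1} (martingale normalisation).
#' Weights are kept in log space; normalise with a shifted exponential
#' (see [validate_driftless()]) because \eqn{\int u^2 ds} can be large
#' when \eqn{c} is small.
#'
#' @param ensemble A [trajectory_ensemble] produced by [simulate_em()]
#'   (its stored increments must be raw Brownian increments).
#' @param u_values Drift from [girsanov_drift()] on the same grid.
#' @param grid The matching [time_grid()].
#' @return Numeric vector of per-path \eqn{\log M_T}.
#' @export
radon_nikodym_weights <- function(ensemble, u_values, grid) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"), is_time_grid(grid))
  if (!identical(ensemble$increments_type, "brownian")) {
    stop("ensemble does not expose raw Brownian increments; use simulate_em().",
         call. = FALSE)
  }
  if (grid$n_steps != ensemble$grid$n_steps ||
      abs(grid$t_end - ensemble$grid$t_end) > 1e-12) {
    stop("grid does not match the ensemble's grid.", call. = FALSE)
  }
  if (length(u_values) != grid$n_steps) {
    stop("`u_values` length must equal the number of grid steps.",
         call. = FALSE)
  }
  stoch <- as.vector(ensemble$increments %*% u_values)
  -stoch - 0.5 * sum(u_values^2) * grid$dt
}

#' Validate driftlessness under the Girsanov measure
#'
#' Operational check of the change-of-measure construction: simulate
#' \eqn{F} under the physical measure P, form \eqn{Y_t = e^{-(a-b)t}F_t},
#' and reweight terminal increments \eqn{Y_T - Y_0} by the Radon--Nikodym
#' weights \eqn{M_T}. Under the new measure Q the process satisfies
#' \eqn{dY = c(t) e^{-(a-b)t} d\tilde B}, so the weighted mean drift must
#' be statistically indistinguishable from zero — GC content "as likely to
#' increase as to decrease" — while the unweighted (P) drift equals
#' \eqn{\int_0^T b e^{-(a-b)s} ds}.
#'
#' Standard errors for the weighted mean use the effective sample size
#' \eqn{(\sum w)^2 / \sum w^2} of the self-normalised weights.
#'
#' @inheritParams simulate_em
#' @param n_steps Grid resolution. Default 200.
#' @return A one-row tibble with the mean weight and its SE, unweighted
#'   and weighted drift estimates with SEs, the closed-form P-drift, the
#'   Novikov diagnostic, the effective sample size, and a `driftless`
#'   flag (|weighted drift| < 4 SE).
#' @examples
#' p <- rate_parameters(a = -2, b = 1, F0 = 0.5)
#' validate_driftless(p, sched_const(0.5), n_paths = 2000, seed = 1)
#' @export
validate_driftless <- function(params, sched, n_paths, seed, n_steps = 200) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(sched, "perturbation_schedule"))
  grid <- time_grid(sched$domain_end, n_steps)
  u <- girsanov_drift(params, sched, grid)
  novikov <- novikov_check(u, grid)
  if (!is.finite(novikov)) {
    stop("Novikov condition fails (divergent exponent); the change of measure is not valid for this schedule.",
         call. = FALSE)
  }
  ens <- simulate_em(params, sched, grid, n_paths, seed)
  log_w <- radon_nikodym_weights(ens, u, grid)
  d <- params$a - params$b
  y <- exp(-d * grid$times[length(grid$times)]) * terminal_values(ens) -
    params$F0
  # shifted-exponential normalisation keeps weights finite in log space
  w <- exp(log_w - max(log_w))
  w <- w / sum(w)
  n_eff <- 1 / sum(w^2)
  mean_w <- mean(exp(log_w))
  se_mean_w <- stats::sd(exp(log_w)) / sqrt(n_paths)
  drift_p <- mean(y)
  se_p <- stats::sd(y) / sqrt(n_paths)
  drift_q <- sum(w * y)
  se_q <- sqrt(sum(w^2 * (y - drift_q)^2))
  b <- params$b
  drift_p_exact <- if (abs(d) < 1e-10) b * grid$t_end else
    b * (exp(-d * grid$t_end) - 1) / (-d)
  tibble::tibble(
    n_paths = as.integer(n_paths), n_steps = as.integer(n_steps),
    mean_weight = mean_w, se_mean_weight = se_mean_w,
    unweighted_drift = drift_p, se_unweighted = se_p,
    closed_form_p_drift = drift_p_exact,
    weighted_drift = drift_q, se_weighted = se_q,
    n_effective = n_eff, novikov = novikov,
    driftless = abs(drift_q) < 4 * se_q)
}

#' Bundle a Girsanov change of measure
#'
#' Convenience constructor collecting the pieces of the change of
#' measure for one simulated ensemble: the tabulated drift \eqn{u(t)},
#' the per-path log Radon--Nikodym weights \eqn{\log M_T}, and the
#' Novikov diagnostic.
#'
#' @param params A [rate_parameters()] object.
#' @param sched A strictly positive [perturbation_schedule()].
#' @param ensemble A [trajectory_ensemble] from [simulate_em()] on the
#'   same grid.
#' @return An object of class `measure_change` with elements `u_values`,
#'   `log_weights`, `novikov_value`, `grid`.
#' @examples
#' p <- rate_parameters(a = -2, b = 1, F0 = 0.5)
#' g <- time_grid(1, 100)
#' ens <- simulate_em(p, sched_const(0.5), g, n_paths = 50, seed = 1)
#' mc <- measure_change(p, sched_const(0.5), ens)
#' mean(exp(mc$log_weights))  # near 1
#' @export
measure_change <- function(params, sched, ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  grid <- ensemble$grid
  u <- girsanov_drift(params, sched, grid)
  nv <- novikov_check(u, grid)
  lw <- radon_nikodym_weights(ensemble, u, grid)
  if (any(!is.finite(lw))) {
    stop("non-finite log-weights; the change of measure is ill-posed here.",
         call. = FALSE)
  }
  structure(list(u_values = u, log_weights = lw, novikov_value = nv,
                 grid = grid),
            class = "measure_change")
}

#' @export
print.measure_change <- function(x, ...) {
  cat(sprintf(
    "<measure_change>  %d paths, Novikov = %.6g, mean weight = %.4f\n",
    length(x$log_weights), x$novikov_value, mean(exp(x$log_weights))))
  invisible(x)
}
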