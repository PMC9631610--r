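#' Mutation-rate parameters of the GC-content model
#'
#' Bundles the AT\eqn{\to}GC mutation-rate constant \eqn{a}, the
#' GC\eqn{\to}AT constant \eqn{b}, and the initial GC fraction \eqn{F_0}
#' of the GC-content stochastic differential equation
#' \deqn{dF_t = (a F_t + b (1 - F_t))\,dt + c(t)\,dB_t.}
#' The biologically motivated regime is \eqn{a - b < 0} (an AT mutational
#' bias, as observed across prokaryotes); constructing parameters with
#' \eqn{a \ge b} requires `allow_ab_regime = TRUE`. All closed forms
#' remain valid in either regime.
#'
#' @param a AT\eqn{\to}GC mutation-rate constant (per unit time).
#' @param b GC\eqn{\to}AT mutation-rate constant (per unit time).
#' @param F0 Initial GC fraction, strictly inside (0, 1) unless
#'   `allow_boundary_F0 = TRUE` (the SNP model uses \eqn{F_0 = 0}).
#' @param allow_ab_regime Permit \eqn{a - b \ge 0}. Default `FALSE`.
#' @param allow_boundary_F0 Permit \eqn{F_0 \in \{0, 1\}}. Default `FALSE`.
#'
#' @return An object of class `rate_parameters`: a named list with
#'   elements `a`, `b`, `F0`.
#' @examples
#' rate_parameters(a = -2, b = 1, F0 = 0.5)
#' @export
rate_parameters <- function(a, b, F0,
                            allow_ab_regime = FALSE,
                            allow_boundary_F0 = FALSE) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) ||
      !is.numeric(b) || length(b) != 1L || !is.finite(b)) {
    stop("`a` and `b` must be finite numeric scalars.", call. = FALSE)
  }
  if (!is.numeric(F0) || length(F0) != 1L || !is.finite(F0)) {
    stop("`F0` must be a finite numeric scalar.", call. = FALSE)
  }
  if (allow_boundary_F0) {
    if (F0 < 0 || F0 > 1) {
      stop("`F0` must lie in [0, 1].", call. = FALSE)
    }
  } else if (F0 <= 0 || F0 >= 1) {
    stop("`F0` must lie strictly inside (0, 1); ",
         "use `allow_boundary_F0 = TRUE` for the F0 = 0 SNP model.",
         call. = FALSE)
  }
  if (a - b >= 0 && !allow_ab_regime) {
    stop("Default regime requires a - b < 0 (AT mutational bias); ",
         "pass `allow_ab_regime = TRUE` to override.", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), F0 = as.numeric(F0)),
            class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat(sprintf(
    "<rate_parameters>  a = %g (AT->GC)  b = %g (GC->AT)  F0 = %g  [a - b = %g]\n",
    x$a, x$b, x$F0, x$a - x$b))
  invisible(x)
}

#' Uniform time grid for trajectory simulation
#'
#' @param t_end End of the (dimensionless) time interval, \eqn{T > 0}.
#' @param n_steps Number of uniform intervals, at least 1.
#'
#' @return An object of class `time_grid` with elements `t_end`,
#'   `n_steps`, `dt`, and `times` (length `n_steps + 1`, from 0 to `t_end`).
#' @examples
#' time_grid(t_end = 1, n_steps = 1000)
#' @export
time_grid <- function(t_end, n_steps) {
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0) {
    stop("`t_end` must be a positive finite scalar.", call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) {
    stop("`n_steps` must be an integer >= 1.", call. = FALSE)
  }
  dt <- t_end / n_steps
  structure(
    list(t_end = as.numeric(t_end), n_steps = n_steps, dt = dt,
         times = seq(0, t_end, length.out = n_steps + 1L)),
    class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid>  [0, %g] in %d uniform steps (dt = %g)\n",
              x$t_end, x$n_steps, x$dt))
  invisible(x)
}

is_time_grid <- function(x) inherits(x, "time_grid")

#' Growth parameters of the stochastic Luria--Delbrueck model
#'
#' Parameters of the geometric-Brownian population-growth model
#' \eqn{P_t = P_0 \exp((k - p^2/2) t + p B_t)} and the associated
#' mutation-count process \eqn{M_t = P_t \mu}.
#'
#' @param P0 Initial population size, positive.
#' @param k Growth-rate constant (per unit time).
#' @param p Noise amplitude (per square-root unit time), non-negative.
#' @param mu Mutations per individual per unit time, non-negative.
#' @param g Genome size in nucleotides (used by [decompose_mutations()]);
#'   optional, a positive integer when supplied.
#'
#' @return An object of class `growth_parameters`.
#' @examples
#' growth_parameters(P0 = 1, k = 1, p = 0.5, mu = 5)
#' @export
growth_parameters <- function(P0, k, p, mu, g = NULL) {
  if (!is.numeric(P0) || length(P0) != 1L || !is.finite(P0) || P0 <= 0) {
    stop("`P0` must be a positive finite scalar.", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k)) {
    stop("`k` must be a finite scalar.", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0) {
    stop("`p` must be a non-negative finite scalar (amplitude).",
         call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop("`mu` must be a non-negative finite scalar.", call. = FALSE)
  }
  if (!is.null(g)) {
    if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 1 ||
        g != round(g)) {
      stop("`g` must be a positive integer (genome size).", call. = FALSE)
    }
    g <- as.numeric(g)
  }
  structure(list(P0 = as.numeric(P0), k = as.numeric(k), p = as.numeric(p),
                 mu = as.numeric(mu), g = g),
            class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat(sprintf("<growth_parameters>  P0 = %g  k = %g  p = %g  mu = %g%s\n",
              x$P0, x$k, x$p, x$mu,
              if (is.null(x$g)) "" else sprintf("  g = %g", x$g)))
  invisible(x)
}
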