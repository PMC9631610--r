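# Shared fixtures: the canonical simulation scenario (a = -2, b = 1,
# F0 = 0.5, T = 1) and its three perturbation schedules, plus independent
# brute-force oracles used to check quadrature-based results.

scenario_params <- function() rate_parameters(a = -2, b = 1, F0 = 0.5)

scenario_schedules <- function() {
  list(sqrt = sched_sqrt(0.5),
       linear_decay = sched_linear_decay(0.5),
       quad_decay = sched_quad_decay(0.5))
}

# Independent composite-trapezoid oracle for the Ito-isometry variance
# integral; deliberately does not reuse variance_gc() internals.
brute_force_variance <- function(a, b, c_fun, t, n_nodes = 1e6) {
  s <- seq(0, t, length.out = n_nodes)
  y <- c_fun(s)^2 * exp(2 * (a - b) * (t - s))
  sum((s[-1] - s[-n_nodes]) * (y[-1] + y[-n_nodes])) / 2
}

# Closed-form variance for constant c (analytic antiderivative).
const_c_variance <- function(a, b, c0, t) {
  d <- a - b
  if (abs(d) < 1e-12) c0^2 * t else c0^2 * (1 - exp(2 * d * t)) / (-2 * d)
}

# Draw a valid AT-bias parameter set (a < b) for property-style loops.
# Parameterised through the equilibrium GC fraction b/(b - a) so the
# trajectory stays inside (0, 1) and no constraint warnings fire.
random_params <- function() {
  gap <- stats::runif(1, 0.5, 4)            # b - a > 0
  equil <- stats::runif(1, 0.1, 0.9)        # b / (b - a)
  b <- equil * gap
  rate_parameters(a = b - gap, b = b, F0 = stats::runif(1, 0.05, 0.95))
}
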