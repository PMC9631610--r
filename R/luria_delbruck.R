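#' Simulate stochastic Luria--Delbrueck mutation counts
#'
#' Setting the GC\eqn{\to}AT rate to zero turns the GC-content equation
#' into stochastic exponential population growth
#' \eqn{dP_t = (k + p W_t) P_t\,dt}; its Ito solution is geometric
#' Brownian motion, and multiplying by the per-capita mutation rate
#' \eqn{\mu} gives the mutation-count process
#' \deqn{M_t = P_0 \mu \exp\big((k - p^2/2)\,t + p B_t\big).}
#' Paths are generated by the exact lognormal update
#' \eqn{M_{i+1} = M_i \exp((k - p^2/2)\Delta s + p \Delta B_i)}, so the
#' ensemble mean converges to \eqn{P_0 \mu e^{kt}} and the variance to
#' \eqn{(P_0\mu)^2 e^{2kt}(e^{p^2 t} - 1)}. As \eqn{k \to p^2/2} the
#' median path flattens while the mean still grows — the regime where
#' random fluctuations dominate mutation accumulation.
#'
#' Counts are continuous intensities, not integers; see
#' [poisson_mutation_counts()] for an integer-valued overlay.
#'
#' @param gp A [growth_parameters()] object.
#' @param grid A [time_grid()].
#' @param n_paths Number of trajectories.
#' @param seed Integer master seed.
#' @return A [trajectory_ensemble] (quantity `"mutation_count"`).
#' @examples
#' gp <- growth_parameters(P0 = 1, k = 1, p = 0.5, mu = 5)
#' ens <- simulate_mutations(gp, time_grid(1, 100), n_paths = 500, seed = 1)
#' mean(terminal_values(ens))  # near 5 * exp(1)
#' @export
simulate_mutations <- function(gp, grid, n_paths, seed) {
  stopifnot(inherits(gp, "growth_parameters"))
  check_sim_args(gp, NULL, grid, n_paths, seed)
  n_paths <- as.integer(n_paths)
  dt <- grid$dt
  drift <- (gp$k - gp$p^2 / 2) * dt
  dB <- draw_increments(n_paths, grid$n_steps, seed) * sqrt(dt)
  m0 <- gp$P0 * gp$mu
  values <- matrix(NA_real_, nrow = n_paths, ncol = grid$n_steps + 1L)
  values[, 1L] <- m0
  m <- rep(m0, n_paths)
  for (i in seq_len(grid$n_steps)) {
    m <- m * exp(drift + gp$p * dB[, i])
    values[, i + 1L] <- m
  }
  new_trajectory_ensemble(grid, values, seed, "exact", "mutation_count",
                          increments = dB, increments_type = "brownian",
                          params = gp)
}

#' Decompose mutation counts into AT and GC components
#'
#' Multiplying the GC-content balance by the genome size \eqn{g} and
#' taking moduli splits the mutation count as
#' \deqn{M^{GC} = |g\,\alpha\,F_t|, \qquad M^{AT} = |g\,\beta\,(1-F_t)|,}
#' with \eqn{M = M^{AT} + M^{GC}}. The absolute values make the split
#' insensitive to the sign convention of the rates (a negative net AT
#' drift still produces a non-negative count). By default \eqn{\alpha,
#' \beta} are the unperturbed constants; callers tracking the white-noise
#' perturbation can pass the perturbed per-instant rates instead.
#'
#' @param g Genome size in nucleotides, at least 1.
#' @param alpha AT\eqn{\to}GC rate at the evaluation instant.
#' @param beta GC\eqn{\to}AT rate at the evaluation instant.
#' @param F GC fraction(s) in `[0, 1]`; vectorised.
#' @return A tibble with columns `at_count`, `gc_count`, `total`
#'   (`total = at_count + gc_count` exactly).
#' @examples
#' decompose_mutations(g = 100, alpha = 2, beta = 1, F = 0.5)
#' @export
decompose_mutations <- function(g, alpha, beta, F) {
  if (!is.numeric(g) || length(g) != 1L || g < 1) {
    stop("`g` must be a genome size >= 1.", call. = FALSE)
  }
  if (any(!is.finite(F)) || any(F < 0 | F > 1)) {
    stop("`F` must lie in [0, 1].", call. = FALSE)
  }
  gc <- abs(g * alpha * F)
  at <- abs(g * beta * (1 - F))
  tibble::tibble(at_count = at, gc_count = gc, total = at + gc)
}

#' Cumulative mutation load
#'
#' Accumulated mutations up to each grid time, the Lebesgue integral
#' \eqn{\int_0^t M_s\,ds} evaluated per path by the composite trapezoid
#' rule. The result is non-decreasing in \eqn{t} and linear in the
#' integrand.
#'
#' @param m Either a [trajectory_ensemble] of mutation counts or a
#'   numeric matrix (`n_paths x (n_steps + 1)`) of non-negative values on
#'   `grid`.
#' @param grid The matching [time_grid()]; taken from the ensemble when
#'   `m` is one.
#' @return A tibble with columns `path_id`, `t`, `cumulative` covering
#'   every grid time.
#' @examples
#' g <- time_grid(1, 100)
#' m <- matrix(5, nrow = 1, ncol = 101)       # constant intensity
#' tail(cumulative_mutations(m, g), 1)        # 5 * t = 5
#' @export
cumulative_mutations <- function(m, grid = NULL) {
  if (inherits(m, "trajectory_ensemble")) {
    grid <- m$grid
    m <- m$values
  }
  stopifnot(is.matrix(m), is_time_grid(grid),
            ncol(m) == grid$n_steps + 1L)
  if (any(m < 0)) {
    stop("mutation intensities must be non-negative.", call. = FALSE)
  }
  dt <- grid$dt
  n <- ncol(m)
  # cumulative trapezoid along each row
  avg <- (m[, -1L, drop = FALSE] + m[, -n, drop = FALSE]) / 2 * dt
  cum <- cbind(0, t(apply(avg, 1L, cumsum)))
  tibble::tibble(
    path_id = rep(seq_len(nrow(m)), each = n),
    t = rep(grid$times, times = nrow(m)),
    cumulative = as.vector(t(cum)))
}

#' Integer mutation counts by Poisson overlay
#'
#' The growth model's mutation counts are continuous intensities. This
#' optional extension draws integer counts as Poisson variates with the
#' path intensity as mean, for fluctuation-test-style analyses that need
#' whole mutations. It is an overlay on the model, not part of it.
#'
#' @param intensity Non-negative numeric vector of intensities.
#' @param seed Integer seed.
#' @return Integer vector of the same length.
#' @export
poisson_mutation_counts <- function(intensity, seed) {
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("`intensity` must be non-negative and finite.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  stats::rpois(length(intensity), intensity)
}
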