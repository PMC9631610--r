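# Path simulation: Euler-Maruyama, exact transition sampling, and the
# discretised stochastic integral, cross-checked against the closed forms.

test_that("noise-free EM reduces to the forward-Euler deterministic path", {
  p <- scenario_params()
  grid <- time_grid(1, 1e4)
  ens <- simulate_em(p, sched_const(0), grid, n_paths = 3, seed = 1)
  # all paths identical
  expect_identical(ens$values[1, ], ens$values[2, ])
  # and within forward-Euler error of the closed form
  expect_lt(max(abs(ens$values[1, ] - deterministic_gc(p, grid$times))),
            1e-3)
})

test_that("noise-free exact simulation has no discretisation error", {
  p <- scenario_params()
  grid <- time_grid(1, 10)
  ens <- simulate_exact(p, sched_const(0), grid, n_paths = 2, seed = 1)
  expect_equal(ens$values[1, ], deterministic_gc(p, grid$times),
               tolerance = 1e-14)
})

test_that("ensembles are bit-reproducible and path-major in the seed", {
  p <- scenario_params()
  grid <- time_grid(1, 50)
  s <- scenario_schedules()$sqrt
  e1 <- simulate_em(p, s, grid, n_paths = 10, seed = 99)
  e2 <- simulate_em(p, s, grid, n_paths = 10, seed = 99)
  expect_identical(e1$values, e2$values)
  # growing the ensemble must not perturb earlier paths
  e3 <- simulate_em(p, s, grid, n_paths = 20, seed = 99)
  expect_identical(e3$values[1:10, ], e1$values)
  ex1 <- simulate_exact(p, s, grid, n_paths = 5, seed = 7)
  ex2 <- simulate_exact(p, s, grid, n_paths = 12, seed = 7)
  expect_identical(ex2$values[1:5, ], ex1$values)
  # the global RNG state is left untouched
  set.seed(1); before <- .Random.seed
  simulate_em(p, s, grid, n_paths = 2, seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("EM terminal mean matches the closed-form expectation", {
  p <- scenario_params()
  ens <- simulate_em(p, scenario_schedules()$sqrt, time_grid(1, 1000),
                     n_paths = 1e4, seed = 11)
  term <- terminal_values(ens)
  se <- stats::sd(term) / sqrt(length(term))
  expect_lt(abs(mean(term) - 0.34163117806131066), 4 * se)
})

test_that("EM terminal variance matches the Ito-isometry integral", {
  p <- scenario_params()
  s <- sched_const(0.5)
  ens <- simulate_em(p, s, time_grid(1, 1000), n_paths = 1e4, seed = 12)
  v <- stats::var(terminal_values(ens))
  expect_lt(abs(v / 0.04156338532597224 - 1), 0.1)
})

test_that("exact and EM simulators agree as mutual oracles", {
  p <- scenario_params()
  for (s in scenario_schedules()) {
    em <- simulate_em(p, s, time_grid(1, 2000), n_paths = 4000, seed = 21)
    ex <- simulate_exact(p, s, time_grid(1, 50), n_paths = 4000, seed = 22)
    tem <- terminal_values(em); tex <- terminal_values(ex)
    se <- sqrt(stats::var(tem) / 4000 + stats::var(tex) / 4000)
    expect_lt(abs(mean(tem) - mean(tex)), 4 * se)
    expect_lt(abs(stats::var(tem) / stats::var(tex) - 1), 0.15)
  }
})

test_that("exact marginals agree with the closed-form mean and variance", {
  p <- scenario_params()
  s <- scenario_schedules()$sqrt
  ens <- simulate_exact(p, s, time_grid(1, 50), n_paths = 1e4, seed = 31)
  term <- terminal_values(ens)
  se <- stats::sd(term) / sqrt(1e4)
  expect_lt(abs(mean(term) - expected_gc(p, 1)), 4 * se)
  expect_lt(abs(stats::var(term) / variance_gc(p, s, 1) - 1), 0.1)
})

test_that("exact terminal law is insensitive to the grid resolution", {
  p <- scenario_params()
  s <- sched_const(0.5)
  coarse <- simulate_exact(p, s, time_grid(1, 1), n_paths = 1e4, seed = 41)
  fine <- simulate_exact(p, s, time_grid(1, 200), n_paths = 1e4, seed = 42)
  ks <- suppressWarnings(
    stats::ks.test(terminal_values(coarse), terminal_values(fine)))
  expect_gt(ks$p.value, 0.01)
})

test_that("EM converges strongly towards the exact map of its own noise", {
  # For each resolution, rebuild the terminal value of the explicit
  # solution from the very increments EM consumed; the RMS gap is the
  # scheme's strong error and must shrink monotonically as dt halves.
  p <- scenario_params()
  s <- scenario_schedules()$sqrt
  d <- p$a - p$b
  rms <- vapply(c(25, 50, 100, 200, 400), function(n_steps) {
    grid <- time_grid(1, n_steps)
    ens <- simulate_em(p, s, grid, n_paths = 2000, seed = 51)
    s_left <- grid$times[-length(grid$times)]
    w <- sched_eval(s, s_left) * exp(d * (1 - s_left))
    ref <- deterministic_gc(p, 1) + as.vector(ens$increments %*% w)
    sqrt(mean((terminal_values(ens) - ref)^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("stochastic integral is centred Gaussian with isometry variance", {
  p <- scenario_params()
  expect_identical(
    stochastic_integral(p, sched_const(0), time_grid(1, 100), 50, seed = 1),
    rep(0, 50))
  z <- stochastic_integral(p, sched_const(0.5), time_grid(1, 2000),
                           n_paths = 2e4, seed = 61)
  se_mean <- stats::sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z)), 4 * se_mean)
  expect_lt(abs(stats::var(z) / 0.04156338532597224 - 1), 0.05)
  # moment-based normality at larger n (sums of normals are normal;
  # only sampling error remains)
  z2 <- stochastic_integral(p, scenario_schedules()$sqrt,
                            time_grid(1, 64), n_paths = 1e5, seed = 62)
  zc <- (z2 - mean(z2)) / stats::sd(z2)
  expect_lt(abs(mean(zc^3)), 0.05)
  expect_lt(abs(mean(zc^4) - 3), 0.1)
})

test_that("degenerate single-step integral reduces to scaled Brownian motion", {
  pe <- rate_parameters(1 - 1e-12, 1, 0.5, allow_ab_regime = TRUE)
  z <- stochastic_integral(pe, sched_const(1), time_grid(1, 1),
                           n_paths = 1e5, seed = 71)
  expect_lt(abs(stats::var(z) - 1), 0.05)  # Var = T = 1
})

test_that("the literal increment reading underestimates the variance", {
  p <- scenario_params()
  z <- stochastic_integral(p, sched_const(0.5), time_grid(1, 100),
                           n_paths = 5000, seed = 81,
                           literal_increment = TRUE)
  # multiplying by ds once more shrinks the variance by ~ds^2
  expect_lt(stats::var(z), 0.04156338532597224 / 100)
})

test_that("path exits from (0, 1) are flagged, and clamping confines paths", {
  p <- rate_parameters(-2, 1, 0.5)
  wild <- sched_const(5)  # huge noise: paths will exit
  ens <- simulate_em(p, wild, time_grid(1, 200), n_paths = 200, seed = 91)
  expect_gt(ens$n_exited, 0)
  cl <- simulate_em(p, wild, time_grid(1, 200), n_paths = 200, seed = 91,
                    clamp = TRUE)
  expect_true(all(cl$values >= 1e-6 & cl$values <= 1 - 1e-6))
})

test_that("invalid grids and arguments are rejected", {
  p <- scenario_params()
  expect_error(time_grid(1, 0), ">= 1")
  expect_error(time_grid(0, 10), "positive")
  expect_error(simulate_em(p, sched_const(0.5, t_end = 0.5),
                           time_grid(1, 10), 5, seed = 1),
               "schedule domain")
  expect_error(simulate_em(p, sched_const(0.5), time_grid(1, 10), 0,
                           seed = 1), "n_paths")
})

test_that("tidy and summary views are consistent with the matrix", {
  p <- scenario_params()
  ens <- simulate_em(p, sched_const(0.5), time_grid(1, 4), 3, seed = 5)
  long <- tidy(ens)
  expect_identical(dim(long), c(15L, 3L))
  expect_identical(long$value[long$path_id == 2], unname(ens$values[2, ]))
  expect_true(all(long$value[long$t == 0] == 0.5))
  summ <- ensemble_summary(ens)
  expect_identical(summ$t, ens$grid$times)
  expect_equal(summ$mean, unname(colMeans(ens$values)))
  expect_equal(summ$closed_form_mean[5], deterministic_gc(p, 1))
  expect_equal(summ$ito_isometry_var[5], variance_gc(p, sched_const(0.5), 1))
})
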