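#' Predicted SNP GC content as a function of core-genome GC content
#'
#' The expectation of the GC-fraction process started at \eqn{F_0 = 0},
#' evaluated with the core-genome GC fraction \eqn{x} in place of time,
#' is the model curve for SNP GC content:
#' \deqn{f(x) = \frac{b}{a-b}\big(e^{(a-b)x} - 1\big),}
#' with the removable \eqn{a = b} singularity handled as
#' \eqn{f(x) = b\,x}. The Brownian term has mean zero, so it plays no
#' role in estimating \eqn{a} and \eqn{b} from (x, f) observations.
#'
#' @param a AT\eqn{\to}GC rate constant.
#' @param b GC\eqn{\to}AT rate constant.
#' @param x Core-genome GC fraction(s) in (0, 1); vectorised. `x = 0` is
#'   accepted and maps to `f = 0`.
#' @return Predicted SNP GC fraction(s).
#' @examples
#' predict_snp_gc(-2, 1, 0.5)  # (1 - exp(-1.5)) / 3
#' @export
predict_snp_gc <- function(a, b, x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`x` must lie in [0, 1].", call. = FALSE)
  }
  gc_mean_closed_form(a, b, 0, x)
}

#' Generate synthetic SNP GC-content observations
#'
#' Draws core-genome GC fractions uniformly on `x_range`, evaluates the
#' SNP model curve [predict_snp_gc()], and adds independent Gaussian
#' observation noise truncated to `[0, 1]`. With `noise_sd = 0` all
#' points lie exactly on the curve. Output is reproducible from `seed`.
#'
#' @inheritParams predict_snp_gc
#' @param n Number of observations, at least 1.
#' @param noise_sd Standard deviation of the additive noise, >= 0.
#' @param x_range Length-2 range inside (0, 1). Default `c(0.05, 0.95)`.
#' @param seed Integer seed.
#' @return A tibble with columns `core_gc`, `snp_gc`.
#' @examples
#' generate_snp_data(-2, 1, n = 5, noise_sd = 0, seed = 1)
#' @export
generate_snp_data <- function(a, b, n, noise_sd, x_range = c(0.05, 0.95),
                              seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1.", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0.", call. = FALSE)
  }
  if (length(x_range) != 2L || x_range[1] >= x_range[2] ||
      x_range[1] <= 0 || x_range[2] >= 1) {
    stop("`x_range` must be an increasing interval inside (0, 1).",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  x <- stats::runif(n, x_range[1], x_range[2])
  f <- predict_snp_gc(a, b, x)
  if (noise_sd > 0) f <- f + stats::rnorm(n, sd = noise_sd)
  tibble::tibble(core_gc = x, snp_gc = pmin(pmax(f, 0), 1))
}

#' Fit mutation-rate constants to SNP GC-content observations
#'
#' Weighted nonlinear least squares for the SNP model curve
#' \eqn{f(x) = \frac{b}{a-b}(e^{(a-b)x} - 1)}: minimises
#' \eqn{\sum_i w_i (f_i - f(x_i; a, b))^2} with the Levenberg--Marquardt
#' algorithm and an analytic Jacobian. The AT-bias regime \eqn{a < b} is
#' enforced by the reparameterisation \eqn{a = b - e^{\delta}} (with
#' \eqn{b} and \eqn{\delta} free), so the constraint can approach but
#' never cross \eqn{a = b}. Approximate standard errors come from the
#' Gauss--Newton covariance, mapped back to \eqn{(a, b)} by the delta
#' method.
#'
#' @param obs A data frame with columns `core_gc` (in (0, 1)) and
#'   `snp_gc`, optionally `weight`; at least 3 rows with at least 3
#'   distinct `core_gc` values.
#' @param init Optional starting values `c(a0, b0)` with `a0 < b0`.
#'   Default `c(-2, 1)`.
#' @param ptol Parameter convergence tolerance. Default `1e-10`.
#' @return An object of class `gc_rate_fit` with elements `a_hat`,
#'   `b_hat`, `rss`, `stderr` (named vector), `converged`, `n_obs`,
#'   `fitted`, `residuals`, `obs`.
#' @examples
#' obs <- generate_snp_data(-2, 1, n = 50, noise_sd = 0, seed = 7)
#' fit <- fit_rates(obs)
#' c(fit$a_hat, fit$b_hat)
#' @export
fit_rates <- function(obs, init = c(-2, 1), ptol = 1e-10) {
  obs <- validate_snp_obs(obs)
  if (length(unique(obs$core_gc)) < 3L) {
    stop("observations are degenerate: at least 3 distinct core_gc values are required to identify (a, b).",
         call. = FALSE)
  }
  if (length(init) != 2L || init[1] >= init[2]) {
    stop("`init` must be c(a0, b0) with a0 < b0.", call. = FALSE)
  }
  x <- obs$core_gc
  f <- obs$snp_gc
  w <- if ("weight" %in% names(obs)) obs$weight else rep(1, nrow(obs))
  sw <- sqrt(w)
  # theta = (b, delta), a = b - exp(delta), d = a - b = -exp(delta)
  theta0 <- c(b = init[2], delta = log(init[2] - init[1]))
  model_d <- function(b, d) {
    if (abs(d) < 1e-12) b * x else b * (exp(d * x) - 1) / d
  }
  resid_fn <- function(theta) {
    d <- -exp(theta[2])
    sw * (f - model_d(theta[1], d))
  }
  jac_fn <- function(theta) {
    b <- theta[1]; d <- -exp(theta[2])
    e <- exp(d * x)
    df_db <- (e - 1) / d
    df_dd <- b * (x * e * d - (e - 1)) / d^2
    # d(d)/d(delta) = -exp(delta) = d
    cbind(-sw * df_db, -sw * df_dd * d)
  }
  ctl <- minpack.lm::nls.lm.control(ptol = ptol, ftol = 1e-12,
                                    maxiter = 500)
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn, jac = jac_fn,
                            control = ctl)
  if (fit$info %in% c(0, 9) || any(!is.finite(fit$par))) {
    stop(sprintf("rate fit did not converge (nls.lm info = %d: %s).",
                 fit$info, fit$message), call. = FALSE)
  }
  b_hat <- unname(fit$par[1])
  delta_hat <- unname(fit$par[2])
  a_hat <- b_hat - exp(delta_hat)
  rss <- sum(resid_fn(fit$par)^2)
  n <- nrow(obs)
  dof <- max(n - 2L, 1L)
  sigma2 <- rss / dof
  J <- jac_fn(fit$par)
  cov_theta <- tryCatch(sigma2 * solve(crossprod(J)),
                        error = function(e) matrix(NA_real_, 2, 2))
  # delta method: a = b - exp(delta) => grad (1, -exp(delta))
  ga <- c(1, -exp(delta_hat))
  se <- c(a = sqrt(drop(t(ga) %*% cov_theta %*% ga)),
          b = sqrt(cov_theta[1, 1]))
  fitted <- predict_snp_gc(a_hat, b_hat, x)
  structure(
    list(a_hat = a_hat, b_hat = b_hat, rss = rss, stderr = se,
         converged = TRUE, n_obs = n, sigma = sqrt(sigma2),
         fitted = fitted, residuals = f - fitted, obs = obs,
         niter = fit$niter),
    class = "gc_rate_fit")
}

validate_snp_obs <- function(obs) {
  if (!is.data.frame(obs) ||
      !all(c("core_gc", "snp_gc") %in% names(obs))) {
    stop("`obs` must be a data frame with columns core_gc and snp_gc.",
         call. = FALSE)
  }
  if (nrow(obs) < 3L) {
    stop("at least 3 observations are required for a 2-parameter fit.",
         call. = FALSE)
  }
  if (any(!is.finite(obs$core_gc)) ||
      any(obs$core_gc <= 0 | obs$core_gc >= 1)) {
    stop("core_gc must be strictly inside (0, 1).", call. = FALSE)
  }
  if (any(!is.finite(obs$snp_gc))) {
    stop("snp_gc must be finite.", call. = FALSE)
  }
  tibble::as_tibble(obs)
}

#' @export
print.gc_rate_fit <- function(x, ...) {
  cat("<gc_rate_fit>  SNP GC-content rate fit\n")
  cat(sprintf("  a (AT->GC) = %.6g  (SE %.3g)\n", x$a_hat, x$stderr["a"]))
  cat(sprintf("  b (GC->AT) = %.6g  (SE %.3g)\n", x$b_hat, x$stderr["b"]))
  cat(sprintf("  RSS = %.6g on %d observations\n", x$rss, x$n_obs))
  invisible(x)
}

#' Tidy a mutation-rate fit
#'
#' @param x A `gc_rate_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @importFrom generics tidy
#' @method tidy gc_rate_fit
#' @export
tidy.gc_rate_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a_hat, x$b_hat),
    std.error = unname(x$stderr[c("a", "b")]))
}

#' One-row summary of a mutation-rate fit
#'
#' @param x A `gc_rate_fit`.
#' @param ... Unused.
#' @return A tibble with `rss`, `sigma`, `n_obs`, `converged`, `niter`.
#' @importFrom generics glance
#' @method glance gc_rate_fit
#' @export
glance.gc_rate_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = x$sigma, n_obs = x$n_obs,
                 converged = x$converged, niter = x$niter)
}

#' Plot SNP observations with the fitted model curve
#'
#' @param object A `gc_rate_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gc_rate_fit
#' @export
autoplot.gc_rate_fit <- function(object, ...) {
  grid <- tibble::tibble(core_gc = seq(min(object$obs$core_gc),
                                       max(object$obs$core_gc),
                                       length.out = 200))
  grid$snp_gc <- predict_snp_gc(object$a_hat, object$b_hat, grid$core_gc)
  ggplot2::ggplot(object$obs, ggplot2::aes(.data$core_gc, .data$snp_gc)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "red", linewidth = 1) +
    ggplot2::labs(x = "core-genome GC fraction x",
                  y = "SNP GC fraction f") +
    ggplot2::theme_minimal()
}

#' @export
plot.gc_rate_fit <- function(x, ...) print(autoplot(x, ...))

#' Read and write SNP GC-content observation tables
#'
#' Two-column tab-delimited text with header `core_gc`, `snp_gc`
#' (an optional third `weight` column is preserved).
#'
#' @param path File path.
#' @param obs A data frame of observations (for writing).
#' @return `read_snp_obs()` returns a validated tibble;
#'   `write_snp_obs()` returns `path` invisibly.
#' @export
read_snp_obs <- function(path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE)
  validate_snp_obs(obs)
}

#' @rdname read_snp_obs
#' @export
write_snp_obs <- function(obs, path) {
  obs <- validate_snp_obs(obs)
  readr::write_tsv(obs, path)
  invisible(path)
}
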