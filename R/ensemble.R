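#' Trajectory ensembles
#'
#' A `trajectory_ensemble` holds a seeded collection of simulated paths on
#' a uniform [time_grid()]: an `n_paths x (n_steps + 1)` value matrix, the
#' driving noise increments (when the scheme is driven by raw Brownian
#' increments), the master seed, the simulation method, and the simulated
#' quantity (`"gc_fraction"`, `"mutation_count"`, or `"population"`).
#' The matrix representation keeps simulation fast; [tidy()] /
#' [tibble::as_tibble()] give the long tabular view `(path_id, t, value)`
#' and [ensemble_summary()] the per-time moments.
#'
#' @name trajectory_ensemble
NULL

new_trajectory_ensemble <- function(grid, values, seed, method, quantity,
                                    increments = NULL,
                                    increments_type = "none",
                                    params = NULL, sched = NULL) {
  stopifnot(is_time_grid(grid), is.matrix(values),
            ncol(values) == grid$n_steps + 1L)
  exited <- rep(FALSE, nrow(values))
  if (identical(quantity, "gc_fraction")) {
    exited <- matrixStats_any_outside(values)
  }
  structure(
    list(grid = grid, values = values, seed = seed, method = method,
         quantity = quantity, increments = increments,
         increments_type = increments_type,
         params = params, sched = sched,
         exited_unit = exited, n_exited = sum(exited)),
    class = "trajectory_ensemble")
}

# row-wise flag: did the path ever leave (0, 1)?
matrixStats_any_outside <- function(v) {
  rowSums(v <= 0 | v >= 1) > 0L
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble>  %d paths of %s on [0, %g] (%d steps), method = %s, seed = %d\n",
    nrow(x$values), x$quantity, x$grid$t_end, x$grid$n_steps, x$method,
    x$seed))
  if (identical(x$quantity, "gc_fraction") && x$n_exited > 0) {
    cat(sprintf("  %d path(s) left (0, 1) at some time.\n", x$n_exited))
  }
  invisible(x)
}

#' Terminal-time values of an ensemble
#'
#' @param ensemble A `trajectory_ensemble`.
#' @return Numeric vector, one value per path, at the final grid time.
#' @export
terminal_values <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  ensemble$values[, ncol(ensemble$values)]
}

#' @importFrom tibble as_tibble
#' @method as_tibble trajectory_ensemble
#' @export
as_tibble.trajectory_ensemble <- function(x, ...) {
  n_paths <- nrow(x$values)
  tibble::tibble(
    path_id = rep(seq_len(n_paths), each = length(x$grid$times)),
    t = rep(x$grid$times, times = n_paths),
    value = as.vector(t(x$values)))
}

#' Tidy a trajectory ensemble into long format
#'
#' @param x A `trajectory_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `path_id`, `t`, `value`.
#' @importFrom generics tidy
#' @method tidy trajectory_ensemble
#' @export
tidy.trajectory_ensemble <- function(x, ...) tibble::as_tibble(x)

#' Per-time summary of an ensemble against its closed forms
#'
#' Computes the cross-path mean and variance at each grid time and, for
#' GC-fraction ensembles with attached parameters and schedule, the
#' closed-form mean ([expected_gc()]) and Ito-isometry variance
#' ([variance_gc()]) for comparison.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param closed_forms Attach closed-form reference columns when
#'   available. Default `TRUE`.
#' @return A tibble with columns `t`, `mean`, `var` and, when available,
#'   `closed_form_mean`, `ito_isometry_var`.
#' @export
ensemble_summary <- function(ensemble, closed_forms = TRUE) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  v <- ensemble$values
  out <- tibble::tibble(
    t = ensemble$grid$times,
    mean = colMeans(v),
    var = apply(v, 2, stats::var))
  if (closed_forms && identical(ensemble$quantity, "gc_fraction") &&
      !is.null(ensemble$params)) {
    out$closed_form_mean <- expected_gc(ensemble$params, out$t)
    if (!is.null(ensemble$sched)) {
      out$ito_isometry_var <- variance_gc(ensemble$params, ensemble$sched,
                                          out$t)
    }
  }
  if (closed_forms && identical(ensemble$quantity, "mutation_count") &&
      !is.null(ensemble$params)) {
    gp <- ensemble$params
    out$closed_form_mean <- gp$P0 * gp$mu * exp(gp$k * out$t)
  }
  out
}

#' Spaghetti plot of a trajectory ensemble
#'
#' Draws every path (thin lines) with the noise-free reference trajectory
#' overlaid as a thick red line, the conventional way of displaying a few
#' realisations of the GC-content or mutation-count process.
#'
#' @param object A `trajectory_ensemble`.
#' @param max_paths Cap on the number of paths drawn. Default 50.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot trajectory_ensemble
#' @export
autoplot.trajectory_ensemble <- function(object, max_paths = 50, ...) {
  long <- tibble::as_tibble(object)
  keep <- seq_len(min(max_paths, nrow(object$values)))
  long <- dplyr::filter(long, .data$path_id %in% keep)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                          group = .data$path_id)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(
      x = "time t",
      y = switch(object$quantity,
                 gc_fraction = "GC fraction F_t",
                 mutation_count = "mutations M_t",
                 "value")) +
    ggplot2::theme_minimal()
  ref <- NULL
  if (identical(object$quantity, "gc_fraction") && !is.null(object$params)) {
    ref <- deterministic_gc(object$params, object$grid$times)
  } else if (identical(object$quantity, "mutation_count") &&
             !is.null(object$params)) {
    gp <- object$params
    ref <- gp$P0 * gp$mu * exp(gp$k * object$grid$times)
  }
  if (!is.null(ref)) {
    refdf <- tibble::tibble(t = object$grid$times, value = ref)
    p <- p + ggplot2::geom_line(
      data = refdf,
      mapping = ggplot2::aes(.data$t, .data$value),
      inherit.aes = FALSE, colour = "red", linewidth = 1)
  }
  p
}

#' @export
plot.trajectory_ensemble <- function(x, ...) print(autoplot(x, ...))
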