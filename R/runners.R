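#' Run a GC-content simulation from a configuration
#'
#' Orchestrates a full simulation run: resolves the configuration,
#' simulates the requested ensemble, and (when `out_prefix` is given)
#' writes `"<prefix>_trajectories.tsv"` in long format
#' (`path_id`, `t`, `value`), `"<prefix>_summary.tsv"` with per-time
#' moments and closed-form references (`t`, `mean`, `var`,
#' `closed_form_mean`, `ito_isometry_var`), and `"<prefix>.log"` with the
#' package version, the fully resolved configuration, the master seed,
#' and a wall-clock stamp — enough to re-derive any table. Output tables
#' are byte-identical across repeated runs with the same seed (the log,
#' which carries the timestamp, is the only file that differs).
#'
#' @param config A config file path or a named list as returned by
#'   [read_run_config()]. Required keys: `a`, `b`, `F0`, `T`, `n_steps`,
#'   `n_paths`, `seed`, `method` (`"em"` or `"exact"`), and a
#'   `[schedule]` block.
#' @param out_prefix Optional output path prefix; with `NULL` nothing is
#'   written.
#' @return Invisibly, a list with `ensemble`, `trajectories` (long
#'   tibble), and `summary` (per-time tibble).
#' @export
run_simulate <- function(config, out_prefix = NULL) {
  cfg <- resolve_config(config)
  for (k in c("a", "b", "F0", "T", "n_steps", "n_paths", "seed")) {
    require_key(cfg, k)
  }
  method <- as.character(cfg$method %||% "em")
  if (!method %in% c("em", "exact")) {
    stop("config key 'method' must be 'em' or 'exact'.", call. = FALSE)
  }
  params <- rate_parameters(cfg$a, cfg$b, cfg$F0, allow_ab_regime = TRUE,
                            allow_boundary_F0 = TRUE)
  sched <- schedule_from_config(cfg$schedule, cfg$T)
  grid <- time_grid(cfg$T, cfg$n_steps)
  sim <- if (method == "em") simulate_em else simulate_exact
  ens <- sim(params, sched, grid, cfg$n_paths, cfg$seed)
  traj <- tibble::as_tibble(ens)
  summ <- ensemble_summary(ens)
  if (!is.null(out_prefix)) {
    readr::write_tsv(traj, paste0(out_prefix, "_trajectories.tsv"))
    readr::write_tsv(summ, paste0(out_prefix, "_summary.tsv"))
    write_run_log(paste0(out_prefix, ".log"), cfg)
  }
  invisible(list(ensemble = ens, trajectories = traj, summary = summ))
}

#' Run a stochastic Luria--Delbrueck simulation from a configuration
#'
#' As [run_simulate()], for the mutation-count process. Required keys:
#' `P0`, `mu`, `k`, `p`, `T`, `n_steps`, `n_paths`, `seed`. The summary
#' includes the noise-free reference \eqn{P_0 \mu e^{kt}}.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with `ensemble`, `trajectories`, `summary`.
#' @export
run_ld <- function(config, out_prefix = NULL) {
  cfg <- resolve_config(config)
  for (k in c("P0", "mu", "k", "p", "T", "n_steps", "n_paths", "seed")) {
    require_key(cfg, k)
  }
  gp <- growth_parameters(P0 = cfg$P0, k = cfg$k, p = cfg$p, mu = cfg$mu)
  grid <- time_grid(cfg$T, cfg$n_steps)
  ens <- simulate_mutations(gp, grid, cfg$n_paths, cfg$seed)
  traj <- tibble::as_tibble(ens)
  summ <- ensemble_summary(ens)
  if (!is.null(out_prefix)) {
    readr::write_tsv(traj, paste0(out_prefix, "_trajectories.tsv"))
    readr::write_tsv(summ, paste0(out_prefix, "_summary.tsv"))
    write_run_log(paste0(out_prefix, ".log"), cfg)
  }
  invisible(list(ensemble = ens, trajectories = traj, summary = summ))
}

#' Fit mutation rates from an observation file
#'
#' Reads a SNP observation table (see [read_snp_obs()]), fits the rate
#' constants with [fit_rates()], and optionally writes a flat
#' `key=value` report.
#'
#' @param file Path to a two-column `core_gc` / `snp_gc` TSV.
#' @param out Optional report path.
#' @return Invisibly, the `gc_rate_fit` object.
#' @export
run_fit <- function(file, out = NULL) {
  obs <- read_snp_obs(file)
  fit <- fit_rates(obs)
  if (!is.null(out)) {
    lines <- c(
      sprintf("a_hat=%.17g", fit$a_hat),
      sprintf("b_hat=%.17g", fit$b_hat),
      sprintf("se_a=%.17g", fit$stderr["a"]),
      sprintf("se_b=%.17g", fit$stderr["b"]),
      sprintf("rss=%.17g", fit$rss),
      sprintf("n_obs=%d", fit$n_obs),
      sprintf("converged=%s", fit$converged))
    writeLines(lines, out)
  }
  invisible(fit)
}

#' Run the Girsanov driftlessness check from a configuration
#'
#' Required keys: `a`, `b`, `F0`, `T`, `n_steps`, `n_paths`, `seed`, and
#' a strictly positive `[schedule]` block. Writes the one-row report of
#' [validate_driftless()] as TSV when `out` is given.
#'
#' @inheritParams run_simulate
#' @param out Optional report path.
#' @return Invisibly, the report tibble.
#' @export
run_girsanov_check <- function(config, out = NULL) {
  cfg <- resolve_config(config)
  for (k in c("a", "b", "F0", "T", "n_steps", "n_paths", "seed")) {
    require_key(cfg, k)
  }
  params <- rate_parameters(cfg$a, cfg$b, cfg$F0, allow_ab_regime = TRUE,
                            allow_boundary_F0 = TRUE)
  sched <- schedule_from_config(cfg$schedule, cfg$T)
  report <- validate_driftless(params, sched, n_paths = cfg$n_paths,
                               seed = cfg$seed, n_steps = cfg$n_steps)
  if (!is.null(out)) {
    readr::write_tsv(report, out)
    write_run_log(paste0(out, ".log"), cfg)
  }
  invisible(report)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    read_run_config(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a file path or a named list.", call. = FALSE)
  }
}

write_run_log <- function(path, cfg) {
  flat <- unlist(cfg)
  writeLines(c(
    sprintf("gcsde_version=%s",
            as.character(utils::packageVersion("gcsde"))),
    sprintf("timestamp=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0(names(flat), "=", vapply(flat, as.character, character(1)))),
    path)
  invisible(path)
}
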