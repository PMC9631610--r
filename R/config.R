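#' Read a flat run configuration file
#'
#' Parses the package's plain-text configuration dialect: one `key = value`
#' pair per line, `#` comments, and an optional `[schedule]` section
#' naming a perturbation schedule (`name = const|sqrt|linear_decay|
#' quad_decay` plus its coefficient `c0` or `kappa`). All values outside
#' the schedule block are scalars; numbers are parsed as doubles.
#'
#' @param path Path to the configuration file.
#' @return A named list; a `schedule` element holds the `[schedule]`
#'   key/values as a named list.
#' @examples
#' cfg <- tempfile(fileext = ".cfg")
#' writeLines(c("a = -2", "b = 1", "[schedule]", "name = const",
#'              "c0 = 0.5"), cfg)
#' read_run_config(cfg)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("malformed config line (expected key = value): '%s'", ln),
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else val
    if (is.null(section)) cfg[[key]] <- parsed
    else cfg[[section]][[key]] <- parsed
  }
  cfg
}

# Build a perturbation_schedule from a config's [schedule] block.
schedule_from_config <- function(spec, t_end) {
  if (is.null(spec) || is.null(spec$name)) {
    stop("config is missing a [schedule] block with a 'name' key.",
         call. = FALSE)
  }
  switch(as.character(spec$name),
    const = sched_const(require_key(spec, "c0"), t_end),
    sqrt = sched_sqrt(require_key(spec, "kappa"), t_end),
    linear_decay = sched_linear_decay(require_key(spec, "kappa"), t_end),
    quad_decay = sched_quad_decay(require_key(spec, "kappa"), t_end),
    stop(sprintf(
      "unknown schedule name '%s' (expected const, sqrt, linear_decay or quad_decay).",
      spec$name), call. = FALSE))
}

require_key <- function(cfg, key, context = "config") {
  if (is.null(cfg[[key]])) {
    stop(sprintf("%s is missing required key '%s'.", context, key),
         call. = FALSE)
  }
  cfg[[key]]
}
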