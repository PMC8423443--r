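#' Write a competition trajectory to CSV
#'
#' One row per solver step with header
#' `t,C_A,C_B,T_A,T_B,N,f_A,f_B`; floating point is written with 10+
#' significant digits so downstream comparisons keep headroom below test
#' tolerances.
#'
#' @param trajectory The `$trajectory` tibble of a
#'   [simulate_competition()] outcome (or the outcome itself).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  if (inherits(trajectory, "competition_outcome")) {
    trajectory <- trajectory$trajectory
  }
  if (is.null(trajectory)) {
    stop("no trajectory recorded; rerun with keep_trajectory = TRUE",
         call. = FALSE)
  }
  df <- as.data.frame(lapply(trajectory, function(x) {
    formatC(x, digits = 12, format = "g")
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV back into a tibble
#' @param path File written by [write_trajectory()].
#' @return A tibble with the trajectory columns.
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write a pairwise invasibility matrix
#'
#' The CSV holds invader investments as rows and resident investments as
#' columns (cells are invasion indices); the companion JSON records the
#' grid, parameters, and the ESS certificate summary when an `ess_result`
#' is supplied.
#'
#' @param x A `toxwar_pip` or `ess_result` object.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_pip <- function(x, csv_path = NULL, json_path = NULL) {
  ess <- NULL
  if (inherits(x, "ess_result")) {
    ess <- x
    x <- x$pip
  }
  stopifnot(inherits(x, "toxwar_pip"))
  if (!is.null(csv_path)) {
    m <- x$I
    df <- data.frame(f_inv = x$f_grid,
                     apply(m, 2, function(col) formatC(col, digits = 12,
                                                       format = "g")),
                     check.names = FALSE)
    names(df) <- c("f_inv", format(x$f_grid))
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- list(
      f_grid = x$f_grid,
      self_fitness = x$self_fitness,
      params = unclass(x$params),
      neutral_band = x$neutral_band
    )
    if (!is.null(ess)) {
      payload$f_star <- ess$f_star
      payload$n_candidates <- ess$n_candidates
      payload$grid_step <- ess$grid_step
      payload$certificate <- ess$certificate
    }
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' Read and resolve a run configuration
#'
#' Configurations are YAML with nested sections `ecology`, `solver`,
#' `strategy_A`, `strategy_B` (plus command-specific sections); unknown
#' keys in `ecology`/`solver` are rejected.  Defaults are the standard
#' parameter set; `write_run_config()` echoes a fully resolved
#' configuration so a run can be reproduced from its output directory.
#'
#' @param path YAML file path.
#' @return A list with `params` ([eco_params]), optional `strategy_A` /
#'   `strategy_B` ([strategy]) and any remaining sections unchanged.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  eco_names <- setdiff(names(formals(eco_params)),
                       c("dt", "t_end", "extinction_threshold",
                         "clamp_threshold"))
  solver_names <- c("dt", "t_end", "extinction_threshold", "clamp_threshold")
  eco <- cfg$ecology %||% list()
  sol <- cfg$solver %||% list()
  bad <- c(setdiff(names(eco), eco_names), setdiff(names(sol), solver_names))
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(eco_params, c(eco, sol))
  out <- list(params = params)
  for (nm in c("strategy_A", "strategy_B")) {
    if (!is.null(cfg[[nm]])) out[[nm]] <- as_strategy(cfg[[nm]])
  }
  extra <- setdiff(names(cfg), c("ecology", "solver", "strategy_A",
                                 "strategy_B"))
  out[extra] <- cfg[extra]
  out
}

#' @rdname read_run_config
#' @param config A list as returned by [read_run_config()] (or with the
#'   same shape).
#' @param path Output YAML path.
#' @export
write_run_config <- function(config, path) {
  p <- unclass(as_eco_params(config$params))
  solver_names <- c("dt", "t_end", "extinction_threshold", "clamp_threshold")
  cfg <- list(ecology = p[setdiff(names(p), solver_names)],
              solver = p[solver_names])
  for (nm in c("strategy_A", "strategy_B")) {
    if (!is.null(config[[nm]])) cfg[[nm]] <- unclass(as_strategy(config[[nm]]))
  }
  extra <- setdiff(names(config), c("params", "strategy_A", "strategy_B"))
  cfg[extra] <- config[extra]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
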