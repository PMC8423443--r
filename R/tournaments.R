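#' Grids of sensing strategies
#'
#' A sensing-grid specification enumerates the strategies of one regulation
#' mode on a regular grid over `f_initial`, `f_induced`, and the threshold.
#' Two reference configurations are provided:
#'
#' * [sensing_grid_invasion()] — the scan used to ask which sensing
#'   strategies stably invade the whole constitutive range: `f` step 0.02,
#'   threshold step 0.002, with `U_N` in `[0, 1]` and `U_TB`, `U_QS` in
#'   `[0, 20]`.
#' * [sensing_grid_diversity()] — the optimisation grid against standing
#'   diversity: `f` step 0.05, `U_N` in `[0, 1]` step 0.02, `U_TB` in
#'   `[0.001, 4]` step 0.0005, `U_QS` in `[0.01, 1.2]` step 0.01.
#'
#' The full grids imply millions of competitions; `scale > 1` coarsens every
#' step proportionally (ranges are kept, the range endpoints always
#' included) for desk-scale runs.
#'
#' @param mode One of `"nutrient_sensing"`, `"toxin_sensing"`,
#'   `"quorum_sensing"`.
#' @param f_step Grid step for `f_initial` and `f_induced`.
#' @param threshold_range Length-2 numeric range for the threshold.
#' @param threshold_step Grid step for the threshold.
#' @param scale Coarsening factor (>= 1) applied to every step.
#' @return A `sensing_grid` object; `strategy_grid()` expands it into a
#'   tibble of strategies ordered lexicographically by
#'   `(f_initial, f_induced, threshold)`.
#' @examples
#' g <- sensing_grid_diversity("toxin_sensing", scale = 40)
#' nrow(strategy_grid(g))
#' @export
sensing_grid <- function(mode, f_step, threshold_range, threshold_step,
                         scale = 1) {
  mode <- match.arg(mode, strategy_modes[-1])
  if (scale < 1) stop("`scale` must be >= 1", call. = FALSE)
  if (f_step <= 0 || threshold_step <= 0) {
    stop("grid steps must be > 0", call. = FALSE)
  }
  structure(
    list(mode = mode,
         f_values = grid_seq(0, 1, f_step * scale),
         threshold_values = grid_seq(threshold_range[1], threshold_range[2],
                                     threshold_step * scale)),
    class = "sensing_grid"
  )
}

# Regular sequence over [lo, hi] that always includes both endpoints.
grid_seq <- function(lo, hi, step) {
  if (step >= hi - lo) return(unique(c(lo, hi)))
  v <- seq(lo, hi, by = step)
  if (hi - v[length(v)] > 1e-12) v <- c(v, hi)
  v
}

#' @rdname sensing_grid
#' @export
sensing_grid_invasion <- function(mode, scale = 1) {
  rng <- switch(mode, nutrient_sensing = c(0, 1), c(0, 20))
  sensing_grid(mode, f_step = 0.02, threshold_range = rng,
               threshold_step = 0.002, scale = scale)
}

#' @rdname sensing_grid
#' @export
sensing_grid_diversity <- function(mode, scale = 1) {
  spec <- switch(mode,
    nutrient_sensing = list(rng = c(0, 1), step = 0.02),
    toxin_sensing    = list(rng = c(0.001, 4), step = 0.0005),
    quorum_sensing   = list(rng = c(0.01, 1.2), step = 0.01),
    stop("unknown sensing mode: ", mode, call. = FALSE)
  )
  sensing_grid(mode, f_step = 0.05, threshold_range = spec$rng,
               threshold_step = spec$step, scale = scale)
}

#' @rdname sensing_grid
#' @export
strategy_grid <- function(spec) {
  stopifnot(inherits(spec, "sensing_grid"))
  g <- tidyr::expand_grid(f_initial = spec$f_values,
                          f_induced = spec$f_values,
                          threshold = spec$threshold_values)
  g$mode <- spec$mode
  g[, c("mode", "f_initial", "f_induced", "threshold")]
}

# Encode a strategy tibble (mode, f_initial, f_induced, threshold or f)
# as the numeric matrix the C++ core takes.
grid_strategy_matrix <- function(g) {
  code <- match(g$mode, strategy_modes) - 1L
  cbind(code,
        if ("f" %in% names(g)) ifelse(is.na(g$f), 0, g$f) else 0,
        g$f_initial, g$f_induced, g$threshold)
}

# Self-competition fitness w(s|s) for each row of a strategy tibble.
self_fitness_grid <- function(strats_mat, params) {
  ev <- eco_vector(params)
  vapply(seq_len(nrow(strats_mat)), function(i) {
    sim_competition_cpp(strats_mat[i, ], strats_mat[i, ], ev, FALSE)$final[1]
  }, numeric(1))
}

#' Which sensing strategies stably invade the whole constitutive range?
#'
#' For every `(f_initial, f_induced)` pair of the sensing grid, asks whether
#' at least one threshold value yields a strategy that stably invades every
#' constitutive investment on `constitutive_grid`: the sensing strategy
#' invades each constitutive resident (`I > 1`) and no constitutive mutant
#' can re-invade the sensing resident.  Pairs with a mixed outcome (mutual
#' invasibility) are tallied separately.
#'
#' @param spec A [sensing_grid] specification.
#' @param constitutive_grid Constitutive investments to invade (default
#'   `f = 0, 0.01, ..., 1`).
#' @param params An [eco_params] object.
#' @param neutral_band Neutrality band around `I = 1`.
#' @return A `toxwar_invasion_map`: `$map` (tibble per
#'   `(f_initial, f_induced)`: `stable`, `n_thresholds_stable`,
#'   `any_mixed`), `$pair_counts` (partition of all strategy-resident pairs
#'   into `invades_stably` / `mixed` / `no_invasion` / `degenerate`), and
#'   `$mixed_rate`, the share of successful forward invasions that can be
#'   re-invaded.
#' @export
invasion_map <- function(spec, constitutive_grid = seq(0, 1, by = 0.01),
                         params = eco_params(), neutral_band = 1e-6) {
  params <- as_eco_params(params)
  if (length(constitutive_grid) == 0) {
    stop("`constitutive_grid` must be non-empty", call. = FALSE)
  }
  g <- strategy_grid(spec)
  if (nrow(g) == 0) stop("empty sensing grid", call. = FALSE)
  smat <- grid_strategy_matrix(g)
  cmat <- grid_strategy_matrix(
    tibble::tibble(mode = "constitutive", f = constitutive_grid,
                   f_initial = 0, f_induced = 0, threshold = 0)
  )
  cross <- cross_final_cpp(smat, cmat, eco_vector(params))
  w_self_c <- self_fitness_grid(cmat, params)
  w_self_s <- self_fitness_grid(smat, params)

  # I_fwd[s, c]: sensing invades constitutive resident;
  # I_bwd[s, c]: constitutive re-invades the sensing resident.
  I_fwd <- sweep(cross$biomass_a, 2, w_self_c, "/")
  I_bwd <- sweep(cross$biomass_b, 1, w_self_s, "/")
  deg <- outer(w_self_s <= 0, w_self_c <= 0, "|")
  I_fwd[, w_self_c <= 0] <- NA_real_
  I_bwd[w_self_s <= 0, ] <- NA_real_

  f <- invades(I_fwd, neutral_band) & !deg
  b <- invades(I_bwd, neutral_band) & !deg
  stable_pair <- f & !b
  mixed_pair <- f & b

  stable_all_c <- rowSums(stable_pair) == length(constitutive_grid)
  res <- g
  res$stable_pairwise <- stable_all_c
  map <- dplyr::summarise(
    dplyr::group_by(res, .data$f_initial, .data$f_induced),
    n_thresholds_stable = sum(.data$stable_pairwise),
    stable = any(.data$stable_pairwise),
    .groups = "drop"
  )
  mixed_by_strategy <- rowSums(mixed_pair) > 0
  mm <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(f_initial = g$f_initial,
                                   f_induced = g$f_induced,
                                   m = mixed_by_strategy),
                    .data$f_initial, .data$f_induced),
    any_mixed = any(.data$m), .groups = "drop"
  )
  map <- dplyr::left_join(map, mm, by = c("f_initial", "f_induced"))

  n_deg <- sum(deg)
  counts <- c(
    invades_stably = sum(stable_pair),
    mixed = sum(mixed_pair),
    no_invasion = sum(!deg) - sum(stable_pair) - sum(mixed_pair),
    degenerate = n_deg
  )
  n_invading <- sum(f)
  structure(
    list(map = map, pair_counts = counts,
         mixed_rate = if (n_invading > 0) counts[["mixed"]] / n_invading else NA_real_,
         n_pairs = length(deg), mode = spec$mode,
         constitutive_grid = constitutive_grid, params = params),
    class = "toxwar_invasion_map"
  )
}

#' @export
print.toxwar_invasion_map <- function(x, ...) {
  cat(sprintf("<toxwar_invasion_map> %s: %d (f_initial, f_induced) cells, %d pairs\n",
              x$mode, nrow(x$map), x$n_pairs))
  cat(sprintf("  cells with a stably-invading threshold: %d\n", sum(x$map$stable)))
  cat(sprintf("  mixed rate among successful invasions: %.3g\n", x$mixed_rate))
  invisible(x)
}

#' @export
tidy.toxwar_invasion_map <- function(x, ...) x$map

#' Optimise a sensing mode against a standing diversity of opponents
#'
#' Every strategy on the sensing grid is competed pairwise against each
#' constitutive opponent in the set; a strategy's fitness is its mean final
#' biomass across those competitions (sums rank identically since the
#' opponent count is fixed).  Returns the argmax strategy; ties are broken
#' toward lower `(f_initial, f_induced, threshold)` in lexicographic order.
#'
#' @param spec A [sensing_grid] specification.
#' @param opponents Numeric vector of constitutive investments (see
#'   [opponent_sets()] for the standard diversity ladder).
#' @param params An [eco_params] object.
#' @return A `toxwar_tournament`: `$winner` (strategy, mean fitness and its
#'   per-opponent biomasses), `$fitness` (per-strategy tibble), and
#'   `$records` (long tibble
#'   `mode, f_initial, f_induced, threshold, opponent_f, final_biomass`).
#' @export
diversity_tournament <- function(spec, opponents, params = eco_params()) {
  params <- as_eco_params(params)
  if (length(opponents) == 0) stop("`opponents` must be non-empty", call. = FALSE)
  g <- strategy_grid(spec)
  smat <- grid_strategy_matrix(g)
  cmat <- grid_strategy_matrix(
    tibble::tibble(mode = "constitutive", f = opponents,
                   f_initial = 0, f_induced = 0, threshold = 0)
  )
  W <- cross_final_cpp(smat, cmat, eco_vector(params))$biomass_a
  fitness <- rowMeans(W)
  best <- which.max(fitness)  # first max = lexicographic lowest
  records <- tidyr::expand_grid(i = seq_len(nrow(g)),
                                j = seq_along(opponents))
  records <- tibble::tibble(
    mode = g$mode[records$i],
    f_initial = g$f_initial[records$i],
    f_induced = g$f_induced[records$i],
    threshold = g$threshold[records$i],
    opponent_f = opponents[records$j],
    final_biomass = W[cbind(records$i, records$j)]
  )
  fit_tbl <- dplyr::mutate(g, mean_fitness = fitness,
                           sum_fitness = fitness * length(opponents))
  winner <- list(
    strategy = strategy_sensing(g$mode[best], g$f_initial[best],
                                g$f_induced[best], g$threshold[best]),
    mean_fitness = fitness[best],
    per_opponent = tibble::tibble(opponent_f = opponents,
                                  final_biomass = W[best, ])
  )
  structure(
    list(winner = winner, fitness = fit_tbl, records = records,
         diversity = length(opponents), mode = spec$mode, params = params),
    class = "toxwar_tournament"
  )
}

#' @export
print.toxwar_tournament <- function(x, ...) {
  cat(sprintf("<toxwar_tournament> %s vs %d opponent(s)\n", x$mode, x$diversity))
  cat("  winner:", format(x$winner$strategy), "\n")
  cat(sprintf("  mean fitness: %.6g gC\n", x$winner$mean_fitness))
  invisible(x)
}

#' @export
tidy.toxwar_tournament <- function(x, ...) x$records

#' @export
glance.toxwar_tournament <- function(x, ...) {
  w <- x$winner$strategy
  tibble::tibble(mode = x$mode, diversity = x$diversity,
                 f_initial = w$f_initial, f_induced = w$f_induced,
                 threshold = w$threshold, mean_fitness = x$winner$mean_fitness)
}

#' Linear model of tournament fitness
#'
#' Fits `F ~ N(alpha_S + beta * D, sigma)` by ordinary least squares, where
#' `F` is the per-competition fitness (final biomass), `S` is a two-level
#' indicator contrasting toxin sensing against the other sensing types
#' (group intercepts `alpha_toxin`, `alpha_other`), and `D` is the number
#' of competitors.  Reports both the intercept ratio and the ratio of
#' fitted group means at the mean diversity level, plus the p-value of the
#' type contrast.
#'
#' @param records Tibble with columns `fitness`, `mode` (sensing mode or a
#'   `type` column with values `"toxin"`/`"other"`), and `D` (number of
#'   competitors).
#' @return A `fitness_regression` with coefficients, `sigma`, the two
#'   fitness ratios, and the underlying `lm` fits.
#' @examples
#' rec <- tibble::tibble(
#'   mode = rep(c("toxin_sensing", "nutrient_sensing"), each = 10),
#'   D = rep(c(1, 3, 5, 7, 9), 4),
#'   fitness = c(rnorm(10, 2), rnorm(10, 1))
#' )
#' fit_fitness_regression(rec)
#' @export
fit_fitness_regression <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"type" %in% names(records)) {
    if (!"mode" %in% names(records)) {
      stop("`records` needs a `mode` or `type` column", call. = FALSE)
    }
    records$type <- ifelse(records$mode == "toxin_sensing", "toxin", "other")
  }
  if (!all(c("fitness", "D") %in% names(records))) {
    stop("`records` needs `fitness` and `D` columns", call. = FALSE)
  }
  if (length(unique(records$type)) < 2 || length(unique(records$D)) < 2) {
    stop("records must span both type groups and >= 2 diversity levels",
         call. = FALSE)
  }
  records$type <- factor(records$type, levels = c("toxin", "other"))
  fit <- stats::lm(fitness ~ 0 + type + D, data = records)
  if (stats::df.residual(fit) <= 0) {
    stop("regression has no residual degrees of freedom", call. = FALSE)
  }
  fit_contrast <- stats::lm(fitness ~ type + D, data = records)
  cf <- stats::coef(fit)
  a_tox <- cf[["typetoxin"]]
  a_oth <- cf[["typeother"]]
  beta <- cf[["D"]]
  d_bar <- mean(records$D)
  p_type <- summary(fit_contrast)$coefficients["typeother", "Pr(>|t|)"]
  structure(
    list(alpha_toxin = a_tox, alpha_other = a_oth, beta = beta,
         sigma = summary(fit)$sigma,
         intercept_ratio = a_tox / a_oth,
         fitness_ratio = (a_tox + beta * d_bar) / (a_oth + beta * d_bar),
         p_value_type = p_type, mean_D = d_bar,
         fit = fit, fit_contrast = fit_contrast, n = nrow(records)),
    class = "fitness_regression"
  )
}

#' @export
print.fitness_regression <- function(x, ...) {
  cat("<fitness_regression>\n")
  cat(sprintf("  alpha_toxin = %.4g, alpha_other = %.4g, beta = %.4g, sigma = %.4g\n",
              x$alpha_toxin, x$alpha_other, x$beta, x$sigma))
  cat(sprintf("  toxin/other fitness ratio at mean D: %.3g (intercept ratio %.3g), p(type) = %.3g\n",
              x$fitness_ratio, x$intercept_ratio, x$p_value_type))
  invisible(x)
}

#' @export
tidy.fitness_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("alpha_toxin", "alpha_other", "beta"),
    estimate = c(x$alpha_toxin, x$alpha_other, x$beta),
    std.error = s[c("typetoxin", "typeother", "D"), "Std. Error"]
  )
}

#' @export
glance.fitness_regression <- function(x, ...) {
  tibble::tibble(
    fitness_ratio = x$fitness_ratio, intercept_ratio = x$intercept_ratio,
    p_value_type = x$p_value_type, sigma = x$sigma, n = x$n
  )
}
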