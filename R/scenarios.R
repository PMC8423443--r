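#' Standing-diversity opponent sets
#'
#' The five diversity levels of constitutive opponents used in the
#' standing-diversity tournaments: a single producer at `f = 0.5`, then
#' increasingly extreme symmetric sets up to nine producers
#' `f = 0.1, 0.2, ..., 0.9`.
#'
#' @return Named list of numeric vectors, one per diversity level
#'   `D = 1, 3, 5, 7, 9`.
#' @examples
#' opponent_sets()[["5"]]
#' @export
opponent_sets <- function() {
  mk <- function(d) seq(0.5 - 0.05 * (d - 1), 0.5 + 0.05 * (d - 1), by = 0.1)
  sets <- lapply(c(1, 3, 5, 7, 9), mk)
  names(sets) <- c("1", "3", "5", "7", "9")
  sets
}

#' Sweep the ESS over one ecological parameter
#'
#' Runs [find_ess()] for each value of a single parameter (all others at
#' their base values) and reports the `f*` sequence with a
#' direction-of-change summary.  Degenerate searches ("none found") are
#' preserved as `NA` rows, not dropped.
#'
#' @param parameter One of `"K_N"`, `"mu_max"`, `"k"`, `"l_T"`, `"N0"`,
#'   `"C0"`, `"t_end"`.
#' @param values Values to sweep.
#' @param base Base [eco_params] object.
#' @param grid_step Grid step passed to [find_ess()].
#' @return A tibble with columns `parameter`, `value`, `f_star`, plus a
#'   `direction` attribute (`"increasing"`, `"decreasing"`,
#'   `"interior_maximum"`, or `"non-monotone"`).
#' @examples
#' \donttest{
#' sweep_ess("k", c(10, 20, 40), grid_step = 0.05)
#' }
#' @export
sweep_ess <- function(parameter, values, base = eco_params(),
                      grid_step = 0.05) {
  parameter <- match.arg(parameter,
                         c("K_N", "mu_max", "k", "l_T", "N0", "C0", "t_end"))
  base <- as_eco_params(base)
  f_star <- vapply(values, function(v) {
    find_ess(set_eco_param(base, parameter, v), grid_step = grid_step)$f_star
  }, numeric(1))
  out <- tibble::tibble(parameter = parameter, value = values,
                        f_star = f_star)
  attr(out, "direction") <- sweep_direction(f_star)
  out
}

sweep_direction <- function(f_star, tol = 1e-9) {
  d <- diff(f_star[!is.na(f_star)])
  if (length(d) == 0) return(NA_character_)
  if (all(d >= -tol)) return("increasing")
  if (all(d <= tol)) return("decreasing")
  peak <- which.max(f_star)
  if (all(diff(f_star[seq_len(peak)]) >= -tol) &&
      all(diff(f_star[peak:length(f_star)]) <= tol)) {
    return("interior_maximum")
  }
  "non-monotone"
}

#' Deterministic fixture competitions
#'
#' A small corpus of named competitions with machine-checkable qualitative
#' expectations, covering the canonical regimes: the classic asymmetric
#' constitutive pair (0.3 beats 0.1), a zero-toxin pair obeying the
#' conservation identity, each sensing mode against the optimal
#' constitutive strategy, a quorum strategy that downregulates at high
#' density, and an extinction-triggering mismatch.
#'
#' @param seed Seed for any randomised fixture members (the corpus itself
#'   is deterministic; the seed fixes auxiliary draws).
#' @return Named list of fixtures: each has `strategy_A`, `strategy_B`,
#'   `params`, and `expected` (one of `"A_wins"`, `"B_wins"`, `"tie"`,
#'   `"conservation"`, `"extinction_B"`, `"downregulates"`).
#' @export
make_fixtures <- function(seed = 1) {
  set.seed(seed)
  p <- eco_params()
  list(
    asymmetric_constitutive = list(
      strategy_A = strategy_constitutive(0.3),
      strategy_B = strategy_constitutive(0.1),
      params = p, expected = "A_wins"
    ),
    zero_toxin_conservation = list(
      strategy_A = strategy_constitutive(0),
      strategy_B = strategy_constitutive(0),
      params = p, expected = "conservation"
    ),
    nutrient_vs_optimal = list(
      # attack-then-disarm: full early investment, shut off once the
      # nutrient pool is half depleted
      strategy_A = strategy_sensing("nutrient_sensing", 0.35, 0, 0.5),
      strategy_B = strategy_constitutive(0.35),
      params = p, expected = "A_wins"
    ),
    toxin_vs_weak = list(
      strategy_A = strategy_sensing("toxin_sensing", 0.01, 0.73, 0.005),
      strategy_B = strategy_constitutive(0.1),
      params = p, expected = "downregulates"
    ),
    quorum_vs_optimal = list(
      strategy_A = strategy_sensing("quorum_sensing", 0.0, 0.6, 0.3),
      strategy_B = strategy_constitutive(0.35),
      params = p, expected = "A_wins"
    ),
    quorum_downregulator = list(
      strategy_A = strategy_sensing("quorum_sensing", 0.6, 0.0, 0.4),
      strategy_B = strategy_constitutive(0.35),
      params = p, expected = "downregulates"
    ),
    extinction = list(
      strategy_A = strategy_constitutive(0.5),
      strategy_B = strategy_constitutive(0.0),
      params = eco_params(k = 40),
      expected = "extinction_B"
    )
  )
}

#' Check a fixture's qualitative expectation
#'
#' Runs the fixture competition and verifies the expected outcome:
#' `A_wins`/`B_wins`/`tie` compare final biomasses; `conservation` checks
#' the invariant `C_A + C_B + mu_max (T_A + T_B + N)` along the trajectory;
#' `extinction_B` checks strain B goes extinct; `downregulates` checks the
#' focal strain's realised investment rises and then falls again.
#'
#' @param fixture One element of [make_fixtures()].
#' @param tol Tolerance for the conservation check.
#' @return `TRUE` (invisibly) if the expectation holds, otherwise an error.
#' @export
check_fixture <- function(fixture, tol = 1e-6) {
  out <- simulate_competition(fixture$strategy_A, fixture$strategy_B,
                              fixture$params, keep_trajectory = TRUE)
  ok <- switch(fixture$expected,
    A_wins = out$local_winner == "A",
    B_wins = out$local_winner == "B",
    tie = out$local_winner == "tie",
    extinction_B = out$extinct_B,
    conservation = {
      tr <- out$trajectory
      tot <- tr$C_A + tr$C_B + fixture$params$mu_max * (tr$T_A + tr$T_B + tr$N)
      max(abs(tot - tot[1])) <= tol
    },
    downregulates = {
      fa <- out$trajectory$f_A
      max(fa) > min(fa) && fa[length(fa)] < max(fa)
    },
    stop("unknown expectation: ", fixture$expected, call. = FALSE)
  )
  if (!ok) stop("fixture expectation `", fixture$expected, "` failed",
                call. = FALSE)
  invisible(TRUE)
}
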