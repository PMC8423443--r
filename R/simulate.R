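#' Right-hand side of the competition ODE system
#'
#' The two strains grow on a shared nutrient pool with Monod kinetics
#' `M = N / (N + K_N)` and divert fractions `f_A`, `f_B` of their uptake
#' into toxin production:
#'
#' \deqn{dC_A/dt = (1 - f_A)\, \mu_{max} M C_A - k T_B C_A}
#' \deqn{dT_A/dt = f_A M C_A - l_T T_A}
#' \deqn{dN/dt   = -M (C_A + C_B)}
#'
#' and symmetrically for strain B.  This pure-R evaluation mirrors the
#' compiled solver kernel and is used for direct checks.
#'
#' @param state Named numeric vector or list with `C_A`, `C_B`, `T_A`,
#'   `T_B`, `N` (all >= 0).
#' @param f_A,f_B Current toxin investments in `[0, 1]`.
#' @param params An [eco_params] object.
#' @return Named numeric vector of time derivatives of the five state
#'   variables.
#' @examples
#' derivatives(c(C_A = 0.1, C_B = 0.1, T_A = 0, T_B = 0, N = 1),
#'             f_A = 0.3, f_B = 0.1, params = eco_params())
#' @export
derivatives <- function(state, f_A, f_B, params = eco_params()) {
  params <- as_eco_params(params)
  s <- as.list(state)
  den <- s$N + params$K_N
  M <- if (den > 0) s$N / den else 0
  c(
    C_A = (1 - f_A) * params$mu_max * M * s$C_A - params$k * s$T_B * s$C_A,
    C_B = (1 - f_B) * params$mu_max * M * s$C_B - params$k * s$T_A * s$C_B,
    T_A = f_A * M * s$C_A - params$l_T * s$T_A,
    T_B = f_B * M * s$C_B - params$l_T * s$T_B,
    N   = -M * (s$C_A + s$C_B)
  )
}

#' Simulate a pairwise competition
#'
#' Integrates the competition ODE system from `t = 0` to `t_end` with an
#' implicit (backward) Euler scheme.  Investments are re-evaluated from the
#' state at the start of every step via [toxin_investment()] and held
#' constant through the step.  After each step, state variables below the
#' clamp threshold are zeroed, then a strain whose biomass falls below the
#' extinction threshold is removed for the rest of the run (its already
#' released toxin continues to decay).  The simulation is deterministic.
#'
#' @param strategy_A,strategy_B [strategy] objects (a bare number is taken
#'   as a constitutive investment).
#' @param params An [eco_params] object.
#' @param keep_trajectory If `TRUE`, attach the full time series.
#' @param substeps Integration substeps per `dt` interval (default 1, the
#'   production configuration).  The regulation, clamp, and extinction
#'   rules are always applied on the `dt` grid; `substeps > 1` refines
#'   only the implicit integration between rule applications, which is
#'   how solver accuracy is verified against the adaptive reference.
#' @return A `competition_outcome` object with final biomasses, extinction
#'   flags, the local winner (`"A"`, `"B"`, or `"tie"`; ties within 1e-9
#'   relative), and optionally `$trajectory`, a tibble with columns
#'   `t, C_A, C_B, T_A, T_B, N, f_A, f_B` (the investments applied during
#'   the step ending at each row).
#' @examples
#' out <- simulate_competition(strategy_constitutive(0.3),
#'                             strategy_constitutive(0.1))
#' out$local_winner
#' @export
simulate_competition <- function(strategy_A, strategy_B,
                                 params = eco_params(),
                                 keep_trajectory = FALSE,
                                 substeps = 1L) {
  params <- as_eco_params(params)
  sa <- as_strategy(strategy_A)
  sb <- as_strategy(strategy_B)
  res <- sim_competition_cpp(strategy_vector(sa), strategy_vector(sb),
                             eco_vector(params, substeps), keep_trajectory)
  traj <- NULL
  if (keep_trajectory) {
    traj <- tibble::as_tibble(as.data.frame(res$trajectory))
    names(traj) <- c("t", "C_A", "C_B", "T_A", "T_B", "N", "f_A", "f_B")
    class(traj) <- c("toxwar_trajectory", class(traj))
  }
  new_competition_outcome(res$final[1], res$final[2],
                          res$extinct[1], res$extinct[2],
                          trajectory = traj,
                          strategy_A = sa, strategy_B = sb, params = params)
}

new_competition_outcome <- function(wA, wB, extA, extB, trajectory = NULL,
                                    strategy_A = NULL, strategy_B = NULL,
                                    params = NULL) {
  structure(
    list(final_biomass_A = wA, final_biomass_B = wB,
         extinct_A = extA, extinct_B = extB,
         local_winner = local_winner(wA, wB),
         trajectory = trajectory,
         strategy_A = strategy_A, strategy_B = strategy_B, params = params),
    class = "competition_outcome"
  )
}

# Tie if final biomasses agree within 1e-9 relative (or both are zero).
local_winner <- function(wA, wB, rel_tol = 1e-9) {
  m <- max(wA, wB)
  if (m == 0 || abs(wA - wB) <= rel_tol * m) return("tie")
  if (wA > wB) "A" else "B"
}

#' @export
print.competition_outcome <- function(x, ...) {
  cat("<competition_outcome>\n")
  cat(sprintf("  A: %s -> final biomass %.6g gC%s\n", format(x$strategy_A),
              x$final_biomass_A, if (x$extinct_A) " (extinct)" else ""))
  cat(sprintf("  B: %s -> final biomass %.6g gC%s\n", format(x$strategy_B),
              x$final_biomass_B, if (x$extinct_B) " (extinct)" else ""))
  cat("  local winner:", x$local_winner, "\n")
  invisible(x)
}

#' @export
tidy.competition_outcome <- function(x, ...) {
  tibble::tibble(
    strain = c("A", "B"),
    strategy = c(format(x$strategy_A), format(x$strategy_B)),
    final_biomass = c(x$final_biomass_A, x$final_biomass_B),
    extinct = c(x$extinct_A, x$extinct_B),
    winner = x$local_winner == c("A", "B")
  )
}

#' Reference solution with an adaptive integrator
#'
#' Re-runs a competition with `deSolve::lsoda` (adaptive step, high order)
#' instead of the implicit-Euler production solver.  Regulation is held
#' piecewise-constant per output interval of width `dt`, and the clamp and
#' extinction rules are applied between intervals, so the two solvers share
#' the regulation semantics and differ only in the integrator.
#'
#' @inheritParams simulate_competition
#' @param rtol,atol Tolerances passed to `deSolve::lsoda`.
#' @return A `competition_outcome` (without trajectory).
#' @export
reference_competition <- function(strategy_A, strategy_B,
                                  params = eco_params(),
                                  rtol = 1e-10, atol = 1e-12) {
  params <- as_eco_params(params)
  sa <- as_strategy(strategy_A)
  sb <- as_strategy(strategy_B)
  y <- c(params$C0_A, params$C0_B, 0, 0, params$N0)
  extA <- FALSE; extB <- FALSE
  n_full <- floor(params$t_end / params$dt + 1e-9)
  rem <- params$t_end - n_full * params$dt
  steps <- c(rep(params$dt, n_full), if (rem > 1e-12) rem)
  for (h in steps) {
    fA <- if (extA) 0 else toxin_investment(sa, y[1], y[4], y[5], params$N0)
    fB <- if (extB) 0 else toxin_investment(sb, y[2], y[3], y[5], params$N0)
    sol <- deSolve::ode(
      y = y, times = c(0, h), func = "toxwar_derivs",
      parms = c(params$K_N, params$mu_max, params$k, params$l_T, fA, fB),
      dllname = "toxwar", initfunc = "toxwar_initmod",
      method = "lsoda", rtol = rtol, atol = atol
    )
    y <- as.numeric(sol[nrow(sol), -1])
    y[y < params$clamp_threshold] <- 0
    if (!extA && y[1] < params$extinction_threshold) { y[1] <- 0; extA <- TRUE }
    if (!extB && y[2] < params$extinction_threshold) { y[2] <- 0; extB <- TRUE }
  }
  new_competition_outcome(y[1], y[2], extA, extB,
                          strategy_A = sa, strategy_B = sb, params = params)
}

#' Compare the production solver against the adaptive reference
#'
#' Runs the same competition with the implicit-Euler solver and with the
#' adaptive reference integrator ([reference_competition()]) and reports
#' the maximum relative deviation of the final biomasses.
#'
#' @inheritParams simulate_competition
#' @return A list with both outcomes, the per-strain relative deviations,
#'   and `max_relative_deviation`.  Deviations are relative to the larger
#'   of the two final biomasses (0 if both solvers agree a strain is gone).
#' @export
validate_against_reference <- function(strategy_A, strategy_B,
                                       params = eco_params(),
                                       substeps = 1L) {
  ie <- simulate_competition(strategy_A, strategy_B, params,
                             substeps = substeps)
  ref <- reference_competition(strategy_A, strategy_B, params)
  rel <- function(a, b) {
    m <- max(abs(a), abs(b))
    if (m == 0) 0 else abs(a - b) / m
  }
  dev <- c(A = rel(ie$final_biomass_A, ref$final_biomass_A),
           B = rel(ie$final_biomass_B, ref$final_biomass_B))
  list(implicit_euler = ie, reference = ref, relative_deviation = dev,
       max_relative_deviation = max(dev))
}
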