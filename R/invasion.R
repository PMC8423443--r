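#' Invasion index of a rare mutant against a resident
#'
#' Metapopulation-level invasion fitness: the resident's fitness `w_res` is
#' its final biomass when competing against itself (the typical patch when
#' the mutant is rare), the invader's fitness `w_inv` is its final biomass
#' in the mixed invader-vs-resident patch, and the invasion index is
#' `I_inv = w_inv / w_res`.  The mutant can invade when `I_inv > 1`.
#'
#' The outcome is also classified by comparing the local result (who makes
#' more biomass inside the mixed patch) with the global one (`I_inv` vs 1):
#' `win_local_win_global`, `lose_local_lose_global`,
#' `win_local_lose_global` (local winner that makes few cells),
#' `lose_local_win_global` (passive mutant that avoids costly war), or
#' `mixed` when either comparison is a tie within the neutrality band.
#'
#' @param invader,resident [strategy] objects.
#' @param params An [eco_params] object.
#' @param neutral_band Half-width of the neutrality band around
#'   `I_inv = 1`; indices within it count as "cannot invade".
#' @return An `invasion_result` with `w_inv`, `w_res`, `I_inv`,
#'   `local_winner`, `outcome_class`, and `degenerate` (`TRUE` when the
#'   resident self-extinguishes so `I_inv` is undefined).
#' @examples
#' invasion_index(strategy_constitutive(0.3), strategy_constitutive(0.1))
#' @export
invasion_index <- function(invader, resident, params = eco_params(),
                           neutral_band = 1e-6) {
  params <- as_eco_params(params)
  invader <- as_strategy(invader)
  resident <- as_strategy(resident)
  res_self <- simulate_competition(resident, resident, params)
  mixed <- simulate_competition(invader, resident, params)
  new_invasion_result(w_inv = mixed$final_biomass_A,
                      w_res = res_self$final_biomass_A,
                      w_res_local = mixed$final_biomass_B,
                      neutral_band = neutral_band,
                      invader = invader, resident = resident)
}

new_invasion_result <- function(w_inv, w_res, w_res_local, neutral_band,
                                invader = NULL, resident = NULL) {
  degenerate <- w_res <= 0
  I_inv <- if (degenerate) NA_real_ else w_inv / w_res
  lw <- local_winner(w_inv, w_res_local)
  structure(
    list(w_inv = w_inv, w_res = w_res, I_inv = I_inv,
         local_winner = c(A = "invader", B = "resident", tie = "tie")[[lw]],
         outcome_class = classify_outcome(I_inv, lw, neutral_band),
         degenerate = degenerate,
         invader = invader, resident = resident),
    class = "invasion_result"
  )
}

classify_outcome <- function(I_inv, local, neutral_band = 1e-6) {
  if (is.na(I_inv)) return(NA_character_)
  if (local == "tie" || abs(I_inv - 1) <= neutral_band) return("mixed")
  loc_win <- local == "A"
  glob_win <- I_inv > 1
  if (loc_win && glob_win) "win_local_win_global"
  else if (!loc_win && !glob_win) "lose_local_lose_global"
  else if (loc_win) "win_local_lose_global"
  else "lose_local_win_global"
}

#' @export
print.invasion_result <- function(x, ...) {
  cat("<invasion_result>\n")
  cat(sprintf("  invader:  %s\n  resident: %s\n",
              format(x$invader), format(x$resident)))
  if (x$degenerate) {
    cat("  degenerate: resident self-extinguishes, I_inv undefined\n")
  } else {
    cat(sprintf("  w_inv = %.6g, w_res = %.6g, I_inv = %.6g (%s)\n",
                x$w_inv, x$w_res, x$I_inv, x$outcome_class))
  }
  invisible(x)
}

#' @export
tidy.invasion_result <- function(x, ...) {
  tibble::tibble(
    invader = format(x$invader), resident = format(x$resident),
    w_inv = x$w_inv, w_res = x$w_res, I_inv = x$I_inv,
    local_winner = x$local_winner, outcome_class = x$outcome_class,
    degenerate = x$degenerate
  )
}

# "invades" under the neutrality band: strictly above 1 + band.
invades <- function(I, neutral_band = 1e-6) {
  !is.na(I) & I > 1 + neutral_band
}

#' Test for stable invasion (with back-invasion)
#'
#' A mutant invades *stably* when it can invade the resident
#' (`I(inv | res) > 1`) and the displaced resident cannot re-invade from
#' rare (`I(res | inv) <= 1`).  When both directions can invade the
#' outcome is `mixed` (mutual invasibility); otherwise `no_invasion`.
#'
#' @inheritParams invasion_index
#' @return A list with `verdict` (`"invades_stably"`, `"no_invasion"`, or
#'   `"mixed"`), the forward and backward indices, and a `degenerate` flag.
#' @export
stable_invasion <- function(invader, resident, params = eco_params(),
                            neutral_band = 1e-6) {
  fwd <- invasion_index(invader, resident, params, neutral_band)
  bwd <- invasion_index(resident, invader, params, neutral_band)
  if (fwd$degenerate || bwd$degenerate) {
    return(list(verdict = NA_character_, I_forward = fwd$I_inv,
                I_backward = bwd$I_inv, degenerate = TRUE))
  }
  f <- invades(fwd$I_inv, neutral_band)
  b <- invades(bwd$I_inv, neutral_band)
  verdict <- if (f && !b) "invades_stably" else if (f && b) "mixed" else "no_invasion"
  list(verdict = verdict, I_forward = fwd$I_inv, I_backward = bwd$I_inv,
       degenerate = FALSE)
}

#' Pairwise invasibility plot over constitutive strategies
#'
#' Computes the full matrix of invasion indices `I(f_inv | f_res)` for a
#' grid of constitutive investments.  Each unordered pair of grid values is
#' simulated once (the competition returns both sides' final biomasses) and
#' resident self-fitnesses are computed once per grid value.  Residents
#' that self-extinguish (`w_res = 0`) yield `NA` columns.
#'
#' @param f_grid Sorted vector of at least two constitutive investments in
#'   `[0, 1]`.
#' @inheritParams invasion_index
#' @return A `toxwar_pip` object: `$f_grid`, `$I` (matrix, rows = invader,
#'   columns = resident), `$w` (final-biomass matrix `w(f_i | f_j)`), and
#'   `$self_fitness`.
#' @examples
#' \donttest{
#' pip <- pairwise_invasibility(seq(0, 1, by = 0.05))
#' }
#' @export
pairwise_invasibility <- function(f_grid, params = eco_params(),
                                  neutral_band = 1e-6) {
  params <- as_eco_params(params)
  if (length(f_grid) < 2 || is.unsorted(f_grid) ||
      any(f_grid < 0 | f_grid > 1)) {
    stop("`f_grid` must be a sorted vector of >= 2 values in [0, 1]",
         call. = FALSE)
  }
  strategies <- lapply(f_grid, strategy_constitutive)
  W <- self_cross_final_cpp(strategy_matrix(strategies), eco_vector(params))
  self_fit <- diag(W)
  I <- sweep(W, 2, self_fit, "/")
  I[, self_fit <= 0] <- NA_real_
  dimnames(I) <- dimnames(W) <- list(invader = format(f_grid),
                                     resident = format(f_grid))
  structure(
    list(f_grid = f_grid, I = I, w = W, self_fitness = self_fit,
         params = params, neutral_band = neutral_band),
    class = "toxwar_pip"
  )
}

#' @export
print.toxwar_pip <- function(x, ...) {
  cat(sprintf("<toxwar_pip> %d x %d grid on [%g, %g]\n",
              length(x$f_grid), length(x$f_grid), min(x$f_grid), max(x$f_grid)))
  ndeg <- sum(x$self_fitness <= 0)
  if (ndeg > 0) cat(" ", ndeg, "degenerate resident(s)\n")
  invisible(x)
}

#' @export
tidy.toxwar_pip <- function(x, ...) {
  grid <- x$f_grid
  tibble::tibble(
    f_inv = rep(grid, times = length(grid)),
    f_res = rep(grid, each = length(grid)),
    w_inv = as.vector(x$w),
    I_inv = as.vector(x$I)
  )
}

# ESS quantifier check on a PIP: f* invades every other non-degenerate
# resident and no other strategy invades it.
ess_candidates <- function(pip) {
  nb <- pip$neutral_band
  ok <- pip$self_fitness > 0
  idx <- which(ok)
  vapply(seq_along(pip$f_grid), function(i) {
    if (!ok[i]) return(FALSE)
    others <- setdiff(idx, i)
    all(invades(pip$I[i, others], nb)) &&
      !any(invades(pip$I[others, i], nb))
  }, logical(1))
}

# Evolutionary attractor on a PIP: among non-degenerate strategies that no
# other grid strategy can invade, the one that invades the most others
# (ties toward lower f).  Coincides with the strict ESS when one exists;
# still defined when a globally uninvadable corner (e.g. the pacifist
# f = 0, which nothing can displace but which displaces nothing) blocks
# the "invades all" quantifier.
ess_attractor <- function(pip) {
  nb <- pip$neutral_band
  ok <- pip$self_fitness > 0
  n <- length(pip$f_grid)
  uninvadable <- vapply(seq_len(n), function(i) {
    ok[i] && !any(invades(pip$I[setdiff(seq_len(n), i), i], nb))
  }, logical(1))
  if (!any(uninvadable)) return(list(index = NA_integer_, strict = FALSE))
  n_invaded <- vapply(seq_len(n), function(i) {
    if (!uninvadable[i]) return(-1L)
    sum(invades(pip$I[i, setdiff(which(ok), i)], nb))
  }, integer(1))
  best <- which.max(n_invaded)
  if (n_invaded[best] <= 0) return(list(index = NA_integer_, strict = FALSE))
  list(index = best, strict = n_invaded[best] == sum(ok) - 1L)
}

#' Evolutionarily stable constitutive investment
#'
#' Grid search for the constitutive toxin investment `f*` via a full
#' pairwise invasibility matrix plus quantifier checks.  The strict ESS
#' certificate requires `I(f* | f') > 1` for every other grid strategy
#' (f* invades all) and `I(f' | f*) <= 1` (nothing invades f*).  When no
#' strategy passes the strict check — which happens when a globally
#' uninvadable but inert corner exists, such as a non-producing resident
#' that nothing can displace and that displaces nothing — the reported
#' `f*` is the evolutionary attractor: the non-degenerate strategy that no
#' other grid strategy can invade and that invades the most others.
#' Self-extinguishing residents are excluded from candidacy.  An optional
#' one-level refinement re-grids at a fifth of the step around the winner.
#'
#' @param params An [eco_params] object.
#' @param grid_step Grid spacing over `[0, 1]`, in `(0, 0.1]`.
#' @param refine If `TRUE`, refine once at `grid_step / 5` in a
#'   one-step neighbourhood of the coarse winner.
#' @param neutral_band Neutrality band around `I = 1` (see
#'   [invasion_index()]).
#' @return An `ess_result`: `$f_star` (`NA` if no uninvadable invader
#'   exists on the grid), `$strict` (`TRUE` when the strict quantifier
#'   certificate held), `$certificate` (per-strategy logical vector of the
#'   strict check), and `$pip`.
#' @examples
#' \donttest{
#' find_ess(eco_params(), grid_step = 0.05)$f_star
#' }
#' @export
find_ess <- function(params = eco_params(), grid_step = 0.01,
                     refine = FALSE, neutral_band = 1e-6) {
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 0.1) {
    stop("`grid_step` must be in (0, 0.1]", call. = FALSE)
  }
  grid <- seq(0, 1, by = grid_step)
  if (grid[length(grid)] < 1 - 1e-12) grid <- c(grid, 1)
  pip <- pairwise_invasibility(grid, params, neutral_band)
  cand <- ess_candidates(pip)
  if (any(cand)) {
    f_star <- pip$f_grid[which(cand)[1]]
    strict <- TRUE
  } else {
    att <- ess_attractor(pip)
    f_star <- if (is.na(att$index)) NA_real_ else pip$f_grid[att$index]
    strict <- att$strict
  }
  out <- structure(
    list(f_star = f_star, strict = strict, certificate = cand, pip = pip,
         grid_step = grid_step, n_candidates = sum(cand)),
    class = "ess_result"
  )
  if (refine && !is.na(f_star)) {
    lo <- max(0, f_star - grid_step)
    hi <- min(1, f_star + grid_step)
    fine <- seq(lo, hi, by = grid_step / 5)
    pip2 <- pairwise_invasibility(fine, params, neutral_band)
    cand2 <- ess_candidates(pip2)
    att2 <- if (any(cand2)) list(index = which(cand2)[1], strict = TRUE)
            else ess_attractor(pip2)
    if (!is.na(att2$index)) {
      out$f_star <- pip2$f_grid[att2$index]
      out$refined <- list(certificate = cand2, pip = pip2,
                          strict = att2$strict)
    }
  }
  out
}

#' @export
print.ess_result <- function(x, ...) {
  cat("<ess_result>\n")
  if (is.na(x$f_star)) {
    cat("  no ESS found on the grid (step", x$grid_step, ")\n")
  } else {
    cat(sprintf("  f* = %g (grid step %g, %s certificate)\n", x$f_star,
                x$grid_step,
                if (x$strict) "strict ESS" else "evolutionary attractor"))
  }
  invisible(x)
}

#' @export
glance.ess_result <- function(x, ...) {
  tibble::tibble(
    f_star = x$f_star, strict = x$strict, grid_step = x$grid_step,
    n_candidates = x$n_candidates,
    n_degenerate = sum(x$pip$self_fitness <= 0)
  )
}
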