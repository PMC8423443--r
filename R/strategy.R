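#' Toxin-production strategies
#'
#' A strategy is a rule mapping the current state of a competition to the
#' fraction `f` of nutrient uptake a strain diverts into toxin production
#' (the remaining `1 - f` fuels growth).  Constitutive strategies fix `f`;
#' regulated strategies switch between `f_initial` and `f_induced` when a
#' cue crosses a threshold:
#'
#' * `nutrient_sensing` — cue is nutrient depletion `N0 - N(t)`, threshold
#'   `U_N` (gN of depletion);
#' * `toxin_sensing` — cue is the opponent's toxin concentration, threshold
#'   `U_TB` (gT);
#' * `quorum_sensing` — cue is the strain's own biomass, threshold `U_QS`
#'   (gC).
#'
#' The switch is a Heaviside step with `H(0) = 1`: at exactly the threshold
#' the induced investment applies.  `f_induced` may be lower than
#' `f_initial`, i.e. the cue can act as a repressor.
#'
#' @param f Fixed investment fraction in `[0, 1]` (constitutive only).
#' @param mode One of `"nutrient_sensing"`, `"toxin_sensing"`,
#'   `"quorum_sensing"`.
#' @param f_initial Investment before the cue crosses the threshold, in
#'   `[0, 1]`.
#' @param f_induced Investment after the cue crosses the threshold, in
#'   `[0, 1]`.
#' @param threshold Trigger level of the cue (>= 0), in the cue's units.
#' @return An object of class `toxwar_strategy`.
#' @examples
#' strategy_constitutive(0.35)
#' strategy_sensing("toxin_sensing", f_initial = 0.01, f_induced = 0.73,
#'                  threshold = 0.05)
#' @name strategy
NULL

strategy_modes <- c("constitutive", "nutrient_sensing", "toxin_sensing",
                    "quorum_sensing")

#' @rdname strategy
#' @export
strategy_constitutive <- function(f) {
  check_fraction(f, "f")
  structure(list(mode = "constitutive", f = f), class = "toxwar_strategy")
}

#' @rdname strategy
#' @export
strategy_sensing <- function(mode, f_initial, f_induced, threshold) {
  mode <- match.arg(mode, strategy_modes[-1])
  check_fraction(f_initial, "f_initial")
  check_fraction(f_induced, "f_induced")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be a single number >= 0", call. = FALSE)
  }
  structure(
    list(mode = mode, f_initial = f_initial, f_induced = f_induced,
         threshold = threshold),
    class = "toxwar_strategy"
  )
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single number in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.toxwar_strategy <- function(x, ...) {
  if (x$mode == "constitutive") {
    cat(sprintf("<strategy> constitutive, f = %g\n", x$f))
  } else {
    cat(sprintf("<strategy> %s, f_initial = %g, f_induced = %g, threshold = %g\n",
                x$mode, x$f_initial, x$f_induced, x$threshold))
  }
  invisible(x)
}

#' @export
format.toxwar_strategy <- function(x, ...) {
  if (x$mode == "constitutive") sprintf("constitutive(f=%g)", x$f)
  else sprintf("%s(%g->%g @ %g)", x$mode, x$f_initial, x$f_induced, x$threshold)
}

as_strategy <- function(s) {
  if (inherits(s, "toxwar_strategy")) return(s)
  if (is.numeric(s) && length(s) == 1) return(strategy_constitutive(s))
  if (is.list(s) && !is.null(s$mode)) {
    if (identical(s$mode, "constitutive")) return(strategy_constitutive(s$f))
    return(strategy_sensing(s$mode, s$f_initial, s$f_induced, s$threshold))
  }
  stop("cannot interpret `", deparse(substitute(s)), "` as a strategy",
       call. = FALSE)
}

# Numeric encoding used by the C++ core: (mode_code, f, f_initial,
# f_induced, threshold); mode codes 0..3 in the order of `strategy_modes`.
strategy_vector <- function(s) {
  s <- as_strategy(s)
  code <- match(s$mode, strategy_modes) - 1L
  if (s$mode == "constitutive") c(code, s$f, 0, 0, 0)
  else c(code, 0, s$f_initial, s$f_induced, s$threshold)
}

# Rows: one encoded strategy per element of a list.
strategy_matrix <- function(strategies) {
  m <- t(vapply(strategies, strategy_vector, numeric(5)))
  dim(m) <- c(length(strategies), 5L)
  m
}

#' Realised toxin investment of a strategy at a given state
#'
#' Evaluates the regulation rule: constitutive strategies return their fixed
#' `f`; sensing strategies return `f_initial` or `f_induced` depending on
#' whether their cue (nutrient depletion `N0 - N`, opponent toxin, or own
#' biomass) has reached the threshold.  At exactly the threshold the induced
#' value applies (`H(0) = 1`).
#'
#' @param strategy A [strategy] object.
#' @param C_own Biomass of the focal strain (gC).
#' @param T_opponent Toxin concentration produced by the opponent (gT).
#' @param N Current nutrient level (gN).
#' @param N0 Initial nutrient of the competition (gN).
#' @return The investment fraction in `[0, 1]`; vectorised over the state
#'   arguments.
#' @examples
#' s <- strategy_sensing("nutrient_sensing", 0, 0.5, threshold = 0.3)
#' toxin_investment(s, C_own = 0.1, T_opponent = 0, N = c(0.8, 0.6), N0 = 1)
#' @export
toxin_investment <- function(strategy, C_own, T_opponent, N, N0) {
  strategy <- as_strategy(strategy)
  n <- max(length(C_own), length(T_opponent), length(N))
  if (strategy$mode == "constitutive") return(rep(strategy$f, n))
  cue <- switch(strategy$mode,
    nutrient_sensing = rep_len(N0, n) - rep_len(N, n),
    toxin_sensing    = rep_len(T_opponent, n),
    quorum_sensing   = rep_len(C_own, n)
  )
  ifelse(cue >= strategy$threshold, strategy$f_induced, strategy$f_initial)
}
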