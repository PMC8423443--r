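#' Ecological and solver parameters for a pairwise competition
#'
#' Bundles the kinetic constants of the resource-competition ODE system,
#' the initial conditions, and the numerical settings of the implicit-Euler
#' solver.  Defaults are the standard parameter set used throughout:
#' Monod saturation `K_N = 5` gN, maximum growth rate `mu_max = 10` /hr,
#' killing efficiency `k = 20` /(gT hr), toxin loss `l_T = 0.1` /hr,
#' initial nutrient `N0 = 1` gN, equal seeding `C0_A = C0_B = 0.1` gC, and
#' a 24 hr competition window.
#'
#' Two stochastic-threshold rules close the continuous model: any state
#' variable falling below `clamp_threshold` is set to 0 (numerical guard
#' against negatives), and a strain whose biomass falls below
#' `extinction_threshold` goes extinct irreversibly (its toxin keeps
#' decaying).
#'
#' @param K_N Nutrient saturation constant (gN).
#' @param mu_max Maximum growth rate (1/hr).
#' @param k Toxin killing efficiency (1/(gT*hr)).
#' @param l_T Toxin loss rate (1/hr).
#' @param N0 Initial nutrient pool (gN).
#' @param C0_A,C0_B Initial biomass of strains A and B (gC).
#' @param t_end Competition duration (hr).
#' @param extinction_threshold Biomass below which a strain is set to zero (gC).
#' @param clamp_threshold Value below which any state variable is set to zero.
#' @param dt Implicit-Euler step size (hr).
#' @return An object of class `eco_params` (a named list).
#' @examples
#' p <- eco_params()
#' p$k
#' eco_params(k = 40, t_end = 6)
#' @export
eco_params <- function(K_N = 5, mu_max = 10, k = 20, l_T = 0.1, N0 = 1,
                       C0_A = 0.1, C0_B = 0.1, t_end = 24,
                       extinction_threshold = 1e-6, clamp_threshold = 1e-8,
                       dt = 0.01) {
  p <- list(
    K_N = K_N, mu_max = mu_max, k = k, l_T = l_T, N0 = N0,
    C0_A = C0_A, C0_B = C0_B, t_end = t_end,
    extinction_threshold = extinction_threshold,
    clamp_threshold = clamp_threshold, dt = dt
  )
  validate_eco_params(p)
  structure(p, class = "eco_params")
}

validate_eco_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter `", nm, "` must be a single finite number",
                             call. = FALSE)
  }
  nonneg <- c("K_N", "mu_max", "k", "l_T", "N0", "C0_A", "C0_B",
              "extinction_threshold", "clamp_threshold")
  for (nm in nonneg) {
    if (p[[nm]] < 0) stop("parameter `", nm, "` must be >= 0", call. = FALSE)
  }
  if (p$t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  if (p$dt <= 0 || p$dt > p$t_end) stop("`dt` must satisfy 0 < dt <= t_end",
                                        call. = FALSE)
  invisible(p)
}

#' @export
print.eco_params <- function(x, ...) {
  cat("<eco_params>\n")
  cat(sprintf("  K_N = %g gN, mu_max = %g /hr, k = %g /(gT*hr), l_T = %g /hr\n",
              x$K_N, x$mu_max, x$k, x$l_T))
  cat(sprintf("  N0 = %g gN, C0_A = %g gC, C0_B = %g gC, t_end = %g hr\n",
              x$N0, x$C0_A, x$C0_B, x$t_end))
  cat(sprintf("  dt = %g hr, extinction < %g, clamp < %g\n",
              x$dt, x$extinction_threshold, x$clamp_threshold))
  invisible(x)
}

as_eco_params <- function(p) {
  if (inherits(p, "eco_params")) return(p)
  if (is.list(p)) return(do.call(eco_params, p))
  stop("`params` must be an `eco_params` object or a named list", call. = FALSE)
}

# Flat numeric vector in the order the C++ core expects; `substeps`
# subdivides each dt interval for the implicit integration while the
# regulation/clamp/extinction rules stay on the dt grid.
eco_vector <- function(p, substeps = 1L) {
  c(p$K_N, p$mu_max, p$k, p$l_T, p$N0, p$C0_A, p$C0_B, p$t_end,
    p$extinction_threshold, p$clamp_threshold, p$dt, as.integer(substeps))
}

# Replace one parameter by name (used by sweeps); "C0" sets both strains.
set_eco_param <- function(p, name, value) {
  if (name == "C0") {
    p$C0_A <- value
    p$C0_B <- value
  } else if (name %in% names(p)) {
    p[[name]] <- value
  } else {
    stop("unknown ecological parameter: ", name, call. = FALSE)
  }
  validate_eco_params(p)
  structure(p, class = "eco_params")
}
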