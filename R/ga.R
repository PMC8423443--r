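#' Default parameter constraints for sensing strategies
#'
#' Investment fractions are bounded in `[0, 1]` for every mode; sensing
#' thresholds are constrained to the observed range of their cue:
#' nutrient depletion `U_N` in `[0, 1]` gN, opponent toxin `U_TB` in
#' `[0, 4]` gT, own biomass `U_QS` in `[0, 1.2]` gC.
#'
#' @return Named list with `f_initial`, `f_induced`, and a `threshold`
#'   range per sensing mode.
#' @export
ga_constraints <- function() {
  list(
    f_initial = c(0, 1),
    f_induced = c(0, 1),
    threshold = list(nutrient_sensing = c(0, 1),
                     toxin_sensing = c(0, 4),
                     quorum_sensing = c(0, 1.2))
  )
}

#' Genetic-algorithm configuration
#'
#' The generation update keeps the population at constant size `n`:
#' the `elite_count` fittest parents are copied unchanged, `mutant_count`
#' offspring are drawn from the parents with probability proportional to
#' fitness and have exactly one uniformly chosen parameter perturbed by a
#' `N(0, mutation_sd)` increment (redrawn until the constraint holds), and
#' `immigrant_count` fresh strategies are drawn uniformly within the
#' constraints.  In mixed-mode tournaments the first `burn_in` generations
#' replace the whole population with immigrants (no selection).
#'
#' @param modes One sensing mode, or all three for a mixed tournament.
#' @param population_size Number of strategies per generation (default 60).
#' @param elite_count Unmutated top parents carried over (default 4).
#' @param mutant_count Fitness-proportional mutated offspring; defaults to
#'   whatever fills the population after elites and immigrants (46 at the
#'   default sizes).
#' @param immigrant_count Fresh random strategies per generation (default 10).
#' @param mutation_sd Standard deviation of the Gaussian parameter
#'   perturbation (default 0.001).
#' @param generations Number of generations (default 100).
#' @param burn_in Selection-free opening generations (default 20 when all
#'   three modes compete, else 0).
#' @param constraints See [ga_constraints()].
#' @param top_k Number of top strategies averaged for reporting (default 4).
#' @param seed Master seed; per-stage sub-streams are derived from it so
#'   that changing one stage's draw count does not perturb the others.
#' @return A `ga_config` object.
#' @export
ga_config <- function(modes = c("nutrient_sensing", "toxin_sensing",
                                "quorum_sensing"),
                      population_size = 60, elite_count = 4,
                      mutant_count = population_size - elite_count -
                        immigrant_count,
                      immigrant_count = 10,
                      mutation_sd = 0.001, generations = 100,
                      burn_in = if (length(modes) > 1) 20 else 0,
                      constraints = ga_constraints(), top_k = 4,
                      seed = 1) {
  modes <- match.arg(modes, strategy_modes[-1], several.ok = TRUE)
  counts <- c(elite_count, mutant_count, immigrant_count)
  if (any(counts < 0) || elite_count + mutant_count + immigrant_count !=
      population_size) {
    stop("elite_count + mutant_count + immigrant_count must equal population_size",
         call. = FALSE)
  }
  if (mutation_sd <= 0) stop("`mutation_sd` must be > 0", call. = FALSE)
  if (generations < 1) stop("`generations` must be >= 1", call. = FALSE)
  structure(
    list(modes = modes, population_size = population_size,
         elite_count = elite_count, mutant_count = mutant_count,
         immigrant_count = immigrant_count, mutation_sd = mutation_sd,
         generations = generations, burn_in = burn_in,
         constraints = constraints, top_k = top_k, seed = seed),
    class = "ga_config"
  )
}

#' @export
print.ga_config <- function(x, ...) {
  cat("<ga_config>\n")
  cat("  modes:", paste(x$modes, collapse = ", "), "\n")
  cat(sprintf("  n = %d (%d elite + %d mutants + %d immigrants), sd = %g\n",
              x$population_size, x$elite_count, x$mutant_count,
              x$immigrant_count, x$mutation_sd))
  cat(sprintf("  %d generations (%d burn-in), seed %d\n",
              x$generations, x$burn_in, x$seed))
  invisible(x)
}

#' Draw a random sensing strategy within constraints
#'
#' `f_initial`, `f_induced`, and the threshold are each drawn uniformly on
#' their constraint interval; with several modes the sensing type is drawn
#' uniformly first.  Uses the current RNG state (seed upstream).
#'
#' @param modes One or more sensing modes.
#' @param constraints See [ga_constraints()].
#' @param n Number of strategies to draw.
#' @return A tibble with columns `mode`, `f_initial`, `f_induced`,
#'   `threshold`.
#' @export
random_strategy <- function(modes, constraints = ga_constraints(), n = 1) {
  modes <- match.arg(modes, strategy_modes[-1], several.ok = TRUE)
  mode <- if (length(modes) == 1) rep(modes, n) else sample(modes, n, replace = TRUE)
  runif_in <- function(rng, m) stats::runif(m, rng[1], rng[2])
  thr <- vapply(mode, function(md) {
    rng <- constraints$threshold[[md]]
    stats::runif(1, rng[1], rng[2])
  }, numeric(1))
  tibble::tibble(
    mode = mode,
    f_initial = runif_in(constraints$f_initial, n),
    f_induced = runif_in(constraints$f_induced, n),
    threshold = unname(thr)
  )
}

#' Round-robin fitness of a strategy population
#'
#' Each strategy competes pairwise against all `n` strategies of the
#' population, including itself; its fitness is the sum of its own final
#' biomass across those `n` competitions.  The `n(n+1)/2` unordered
#' competitions are each simulated once.
#'
#' @param population Tibble of strategies (columns `mode`, `f_initial`,
#'   `f_induced`, `threshold`).
#' @param params An [eco_params] object.
#' @return Numeric fitness vector of length `n`.
#' @export
evaluate_population <- function(population, params = eco_params()) {
  params <- as_eco_params(params)
  W <- self_cross_final_cpp(grid_strategy_matrix(population),
                            eco_vector(params))
  rowSums(W)
}

#' One generation update of the genetic algorithm
#'
#' Applies the elitism / fitness-proportional mutation / immigration rule
#' described in [ga_config()].  Elites are byte-identical copies of the top
#' parents (ties broken by index).  When every fitness is zero, selection
#' falls back to uniform sampling (with a message).
#'
#' @param population Tibble of strategies.
#' @param fitness Non-negative fitness vector from [evaluate_population()].
#' @param config A [ga_config()].
#' @param stage_seeds Optional integer vector of length 3 seeding the
#'   selection, mutation, and immigration sub-streams.
#' @return The next-generation population tibble (same size).
#' @export
next_generation <- function(population, fitness, config,
                            stage_seeds = NULL) {
  n <- nrow(population)
  stopifnot(length(fitness) == n, n == config$population_size)
  elite_idx <- order(-fitness)[seq_len(config$elite_count)]
  elites <- population[elite_idx, ]

  if (!is.null(stage_seeds)) set.seed(stage_seeds[1])
  if (all(fitness <= 0)) {
    message("all fitnesses are zero; falling back to uniform selection")
    sel <- sample.int(n, config$mutant_count, replace = TRUE)
  } else {
    sel <- sample.int(n, config$mutant_count, replace = TRUE, prob = fitness)
  }
  mutants <- population[sel, ]

  if (!is.null(stage_seeds)) set.seed(stage_seeds[2])
  if (config$mutant_count > 0) {
    which_par <- sample.int(3, config$mutant_count, replace = TRUE)
    pars <- c("f_initial", "f_induced", "threshold")
    for (i in seq_len(config$mutant_count)) {
      pname <- pars[which_par[i]]
      rng <- if (pname == "threshold") {
        config$constraints$threshold[[mutants$mode[i]]]
      } else {
        config$constraints[[pname]]
      }
      val <- mutants[[pname]][i]
      new <- val + stats::rnorm(1, 0, config$mutation_sd)
      tries <- 1
      while ((new < rng[1] || new > rng[2]) && tries < 1000) {
        new <- val + stats::rnorm(1, 0, config$mutation_sd)
        tries <- tries + 1
      }
      if (new < rng[1] || new > rng[2]) new <- min(max(new, rng[1]), rng[2])
      mutants[[pname]][i] <- new
    }
  }

  if (!is.null(stage_seeds)) set.seed(stage_seeds[3])
  immigrants <- if (config$immigrant_count > 0) {
    random_strategy(config$modes, config$constraints,
                    n = config$immigrant_count)
  } else {
    population[0, ]
  }
  dplyr::bind_rows(elites, mutants, immigrants)
}

# Reference starting points for mixed tournaments: each type opens at its
# within-type evolutionary optimum (f values from single-type runs of this
# framework); thresholds default to the midpoint of the constraint range.
#' Within-type optimum strategies used to seed mixed tournaments
#' @param constraints See [ga_constraints()].
#' @return Tibble of one strategy per sensing mode.
#' @export
within_type_optima <- function(constraints = ga_constraints()) {
  midpoint <- vapply(constraints$threshold, mean, numeric(1))
  tibble::tibble(
    mode = c("nutrient_sensing", "quorum_sensing", "toxin_sensing"),
    f_initial = c(0.05, 0.11, 0.01),
    f_induced = c(0.50, 0.60, 0.73),
    threshold = unname(midpoint[c("nutrient_sensing", "quorum_sensing",
                                  "toxin_sensing")])
  )
}

#' Run the genetic algorithm
#'
#' Iterates evaluate / record / update for `config$generations` rounds.
#' Within-type runs start from a uniform random population; mixed runs
#' start every individual at its type's within-type optimum (types
#' assigned in rotation) and spend the first `burn_in` generations without
#' selection, replacing the whole population with immigrants.  One master
#' seed drives derived sub-streams for initialisation, selection, mutation,
#' and immigration.
#'
#' @param config A [ga_config()].
#' @param params An [eco_params] object.
#' @param init Optional starting population tibble (overrides the default
#'   initialisation).
#' @return A `ga_history`: `$history` (per-generation, per-strategy
#'   records), `$summary` (per-generation means of the `top_k` fittest
#'   strategies' parameters), `$type_summary` (per-generation population
#'   fraction and mean fitness per sensing type), `$final` (top-strategy
#'   parameter means at the last generation, per mode), and `$config`.
#' @export
run_ga <- function(config, params = eco_params(), init = NULL) {
  stopifnot(inherits(config, "ga_config"))
  params <- as_eco_params(params)
  n <- config$population_size
  gens <- config$generations

  set.seed(config$seed)
  seed_pool <- sample.int(.Machine$integer.max - 1L, 1L + 3L * gens)
  init_seed <- seed_pool[1]
  stage_seeds <- matrix(seed_pool[-1], ncol = 3, byrow = TRUE)

  if (is.null(init)) {
    set.seed(init_seed)
    if (length(config$modes) > 1) {
      opt <- within_type_optima(config$constraints)
      opt <- opt[opt$mode %in% config$modes, ]
      pop <- opt[rep_len(seq_len(nrow(opt)), n), ]
    } else {
      pop <- random_strategy(config$modes, config$constraints, n = n)
    }
  } else {
    pop <- tibble::as_tibble(init)
    stopifnot(nrow(pop) == n)
  }

  history <- vector("list", gens)
  summaries <- vector("list", gens)
  type_sum <- vector("list", gens)
  for (g in seq_len(gens)) {
    fitness <- evaluate_population(pop, params)
    history[[g]] <- dplyr::mutate(pop, generation = g,
                                  strategy_id = dplyr::row_number(),
                                  fitness = fitness)
    top <- order(-fitness)[seq_len(min(config$top_k, n))]
    summaries[[g]] <- tibble::tibble(
      generation = g,
      f_initial = mean(pop$f_initial[top]),
      f_induced = mean(pop$f_induced[top]),
      threshold = mean(pop$threshold[top]),
      best_fitness = max(fitness)
    )
    type_sum[[g]] <- dplyr::summarise(
      dplyr::group_by(history[[g]], .data$mode),
      fraction = dplyr::n() / n,
      mean_fitness = mean(.data$fitness), .groups = "drop"
    )
    type_sum[[g]]$generation <- g

    if (g < gens) {
      if (g <= config$burn_in) {
        set.seed(stage_seeds[g, 3])
        pop <- random_strategy(config$modes, config$constraints, n = n)
      } else {
        pop <- next_generation(pop, fitness, config,
                               stage_seeds = stage_seeds[g, ])
      }
    }
  }

  last <- history[[gens]]
  final <- dplyr::summarise(
    dplyr::group_by(
      dplyr::slice_max(last, .data$fitness, n = config$top_k,
                       with_ties = FALSE),
      .data$mode
    ),
    f_initial = mean(.data$f_initial), f_induced = mean(.data$f_induced),
    threshold = mean(.data$threshold), n_top = dplyr::n(), .groups = "drop"
  )

  structure(
    list(history = dplyr::bind_rows(history),
         summary = dplyr::bind_rows(summaries),
         type_summary = dplyr::bind_rows(type_sum),
         final = final, config = config, params = params),
    class = "ga_history"
  )
}

#' @export
print.ga_history <- function(x, ...) {
  cat(sprintf("<ga_history> %d generations, n = %d, modes: %s\n",
              x$config$generations, x$config$population_size,
              paste(x$config$modes, collapse = ", ")))
  cat("  final top-strategy means:\n")
  print(x$final)
  invisible(x)
}

#' @export
tidy.ga_history <- function(x, ...) x$summary

#' @export
glance.ga_history <- function(x, ...) {
  dplyr::mutate(x$final, generations = x$config$generations,
                population_size = x$config$population_size,
                seed = x$config$seed)
}
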