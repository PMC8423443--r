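# Small, fast GA configuration used across these tests.
tiny_config <- function(seed = 1, ...) {
  ga_config(modes = "toxin_sensing", population_size = 6, elite_count = 2,
            mutant_count = 3, immigrant_count = 1, generations = 3,
            seed = seed, ...)
}

test_that("config invariants are enforced", {
  expect_error(ga_config(population_size = 10, elite_count = 4,
                         mutant_count = 4, immigrant_count = 1),
               "must equal")
  expect_error(ga_config(mutation_sd = 0), "mutation_sd")
})

test_that("random strategies are uniform within their constraints", {
  set.seed(5)
  draws <- random_strategy("quorum_sensing", n = 10000)
  expect_true(all(draws$threshold >= 0 & draws$threshold <= 1.2))
  # mean of U(0, 1.2) is 0.6 with se = 1.2/sqrt(12)/sqrt(n)
  se <- 1.2 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(draws$threshold) - 0.6), 3 * se)
  expect_lt(abs(mean(draws$f_initial) - 0.5), 3 * (1 / sqrt(12)) / sqrt(10000))

  # degenerate interval pins the parameter
  cons <- ga_constraints()
  cons$f_initial <- c(0.5, 0.5)
  d2 <- random_strategy("toxin_sensing", cons, n = 50)
  expect_true(all(d2$f_initial == 0.5))

  # mixed draws pick each type with equal probability
  set.seed(6)
  d3 <- random_strategy(c("nutrient_sensing", "toxin_sensing",
                          "quorum_sensing"), n = 3000)
  freq <- table(d3$mode) / 3000
  se3 <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se3))
})

test_that("population fitness equals hand-assembled pairwise sums", {
  pop <- tibble::tibble(
    mode = c("toxin_sensing", "nutrient_sensing", "quorum_sensing"),
    f_initial = c(0.0, 0.3, 0.1),
    f_induced = c(0.6, 0.0, 0.5),
    threshold = c(0.05, 0.5, 0.3)
  )
  fit <- evaluate_population(pop)
  strat <- lapply(seq_len(3), function(i)
    strategy_sensing(pop$mode[i], pop$f_initial[i], pop$f_induced[i],
                     pop$threshold[i]))
  manual <- numeric(3)
  for (i in 1:3) {
    for (j in 1:3) {
      manual[i] <- manual[i] +
        simulate_competition(strat[[i]], strat[[j]])$final_biomass_A
    }
  }
  expect_equal(fit, manual, tolerance = 1e-12)
})

test_that("identical strategies earn identical fitness", {
  pop <- tibble::tibble(mode = "toxin_sensing", f_initial = 0.05,
                        f_induced = 0.6, threshold = 0.1)[rep(1, 4), ]
  fit <- evaluate_population(pop)
  expect_true(all(fit == fit[1]))
})

test_that("generation update: elites are exact copies, size is conserved", {
  cfg <- tiny_config()
  set.seed(3)
  pop <- random_strategy("toxin_sensing", n = 6)
  fit <- c(5, 1, 4, 2, 0.5, 0.1)
  nxt <- next_generation(pop, fit, cfg, stage_seeds = c(11, 12, 13))
  expect_identical(nrow(nxt), 6L)
  expect_identical(nxt[1, ], pop[1, ])  # top fitness
  expect_identical(nxt[2, ], pop[3, ])  # second
})

test_that("a monopolist parent supplies every selected offspring", {
  cfg <- tiny_config()
  set.seed(4)
  pop <- random_strategy("toxin_sensing", n = 6)
  fit <- c(0, 0, 1, 0, 0, 0)
  nxt <- next_generation(pop, fit, cfg, stage_seeds = c(21, 22, 23))
  mutants <- nxt[3:5, ]  # after 2 elites, before 1 immigrant
  for (r in 1:3) {
    diffs <- abs(unlist(mutants[r, -1]) - unlist(pop[3, -1]))
    expect_identical(mutants$mode[r], pop$mode[3])
    expect_identical(sum(diffs > 0), 1L)            # exactly one mutated
    expect_lt(max(diffs), 20 * cfg$mutation_sd)     # by a small increment
  }
})

test_that("all-zero fitness falls back to uniform selection with a message", {
  cfg <- tiny_config()
  set.seed(8)
  pop <- random_strategy("toxin_sensing", n = 6)
  expect_message(next_generation(pop, rep(0, 6), cfg,
                                 stage_seeds = c(31, 32, 33)),
                 "uniform")
})

test_that("mutation respects constraints via redraws", {
  cons <- ga_constraints()
  cfg <- ga_config(modes = "quorum_sensing", population_size = 6,
                   elite_count = 2, mutant_count = 3, immigrant_count = 1,
                   generations = 2, mutation_sd = 0.5, seed = 1,
                   constraints = cons)
  set.seed(9)
  pop <- random_strategy("quorum_sensing", n = 6)
  pop$f_initial <- 0.001  # near the boundary; large sd forces redraws
  nxt <- next_generation(pop, rep(1, 6), cfg, stage_seeds = c(41, 42, 43))
  expect_true(all(nxt$f_initial >= 0 & nxt$f_initial <= 1))
  expect_true(all(nxt$threshold >= 0 & nxt$threshold <= 1.2))
})

test_that("runs are reproducible from the master seed", {
  p <- eco_params(t_end = 6)
  h1 <- run_ga(tiny_config(seed = 42), p)
  h2 <- run_ga(tiny_config(seed = 42), p)
  expect_identical(h1$history, h2$history)
  h3 <- run_ga(tiny_config(seed = 43), p)
  expect_false(identical(h3$history$fitness, h1$history$fitness))
})

test_that("population size and records stay consistent across generations", {
  h <- run_ga(tiny_config(seed = 2), eco_params(t_end = 6))
  counts <- table(h$history$generation)
  expect_true(all(counts == 6))
  expect_identical(nrow(h$summary), 3L)
  expect_true(all(h$type_summary$fraction == 1))  # single-mode run
})

test_that("mixed tournaments start from within-type optima and burn in", {
  cfg <- ga_config(population_size = 6, elite_count = 2, mutant_count = 3,
                   immigrant_count = 1, generations = 3, burn_in = 1,
                   seed = 77)
  h <- run_ga(cfg, eco_params(t_end = 6))
  gen1 <- h$history[h$history$generation == 1, ]
  opt <- within_type_optima()
  expect_true(all(gen1$f_induced %in% opt$f_induced))
  # after burn-in the population was replaced by random immigrants
  gen2 <- h$history[h$history$generation == 2, ]
  expect_false(any(gen2$f_induced %in% opt$f_induced))
})
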