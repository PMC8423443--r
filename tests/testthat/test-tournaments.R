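test_that("sensing grids honour ranges, endpoints, and scaling", {
  g <- sensing_grid("toxin_sensing", f_step = 0.25, threshold_range = c(0.001, 4),
                    threshold_step = 1)
  tb <- strategy_grid(g)
  expect_true(all(tb$f_initial >= 0 & tb$f_initial <= 1))
  expect_equal(range(tb$threshold), c(0.001, 4))
  gs <- sensing_grid("toxin_sensing", f_step = 0.25, threshold_range = c(0.001, 4),
                     threshold_step = 1, scale = 2)
  expect_lt(nrow(strategy_grid(gs)), nrow(tb))
  expect_error(sensing_grid("toxin_sensing", 0, c(0, 1), 0.1), "steps")
})

test_that("invasion_map equals a brute-force triple loop on a toy grid", {
  spec <- sensing_grid("nutrient_sensing", f_step = 0.5,
                       threshold_range = c(0.2, 0.6), threshold_step = 0.4)
  cgrid <- c(0.2, 0.5)
  m <- invasion_map(spec, cgrid)

  g <- strategy_grid(spec)
  brute <- vapply(seq_len(nrow(g)), function(i) {
    s <- strategy_sensing(g$mode[i], g$f_initial[i], g$f_induced[i],
                          g$threshold[i])
    all(vapply(cgrid, function(fc) {
      identical(stable_invasion(s, strategy_constitutive(fc))$verdict,
                "invades_stably")
    }, logical(1)))
  }, logical(1))
  brute_map <- tapply(brute, list(g$f_initial, g$f_induced), any)

  for (r in seq_len(nrow(m$map))) {
    expect_identical(
      m$map$stable[r],
      unname(brute_map[as.character(m$map$f_initial[r]),
                       as.character(m$map$f_induced[r])])
    )
  }
  # verdict partition covers every pair exactly once
  expect_identical(sum(m$pair_counts), m$n_pairs)
})

test_that("a sensing strategy degenerate to the resident cannot invade it", {
  s <- strategy_sensing("quorum_sensing", 0.3, 0.3, 0.5)
  v <- stable_invasion(s, strategy_constitutive(0.3))
  expect_identical(v$verdict, "no_invasion")
})

test_that("adding threshold values never shrinks the stable set", {
  cgrid <- c(0.3, 0.6)
  spec1 <- sensing_grid("nutrient_sensing", f_step = 0.5,
                        threshold_range = c(0.5, 0.5), threshold_step = 1)
  spec2 <- sensing_grid("nutrient_sensing", f_step = 0.5,
                        threshold_range = c(0.3, 0.7), threshold_step = 0.2)
  m1 <- invasion_map(spec1, cgrid)
  m2 <- invasion_map(spec2, cgrid)
  joined <- merge(m1$map, m2$map, by = c("f_initial", "f_induced"))
  expect_true(all(!joined$stable.x | joined$stable.y))
})

test_that("diversity tournament returns the verified argmax, deterministically", {
  spec <- sensing_grid("toxin_sensing", f_step = 0.25,
                       threshold_range = c(0.001, 2), threshold_step = 1)
  opp <- c(0.4, 0.5, 0.6)
  t1 <- diversity_tournament(spec, opp)
  t2 <- diversity_tournament(spec, opp)
  expect_identical(t1$winner$mean_fitness, t2$winner$mean_fitness)
  expect_identical(format(t1$winner$strategy), format(t2$winner$strategy))

  # winner's fitness is >= every grid strategy's, via the records table
  per <- tapply(t1$records$final_biomass,
                interaction(t1$records$f_initial, t1$records$f_induced,
                            t1$records$threshold), mean)
  expect_gte(t1$winner$mean_fitness + 1e-12, max(per))

  # records agree with direct simulation for a spot-checked strategy
  w <- t1$winner$strategy
  direct <- simulate_competition(w, strategy_constitutive(0.4))$final_biomass_A
  rec <- t1$records[t1$records$f_initial == w$f_initial &
                    t1$records$f_induced == w$f_induced &
                    t1$records$threshold == w$threshold &
                    t1$records$opponent_f == 0.4, ]
  expect_identical(rec$final_biomass, direct)
})

test_that("fitness regression recovers known simulated coefficients", {
  set.seed(7)
  n <- 200
  truth <- list(a_tox = 2, a_oth = 1, beta = -0.05, sigma = 0.01)
  rec <- tibble::tibble(
    mode = sample(c("toxin_sensing", "nutrient_sensing", "quorum_sensing"),
                  n, replace = TRUE),
    D = sample(c(1, 3, 5, 7, 9), n, replace = TRUE)
  )
  a <- ifelse(rec$mode == "toxin_sensing", truth$a_tox, truth$a_oth)
  rec$fitness <- rnorm(n, a + truth$beta * rec$D, truth$sigma)
  fit <- fit_fitness_regression(rec)
  est <- tidy(fit)
  expect_lt(abs(est$estimate[est$term == "alpha_toxin"] - truth$a_tox),
            3 * est$std.error[est$term == "alpha_toxin"])
  expect_lt(abs(est$estimate[est$term == "alpha_other"] - truth$a_oth),
            3 * est$std.error[est$term == "alpha_other"])
  expect_lt(abs(est$estimate[est$term == "beta"] - truth$beta),
            3 * est$std.error[est$term == "beta"])
  expect_lt(fit$p_value_type, 0.001)
})

test_that("regression estimates tighten as the sample grows", {
  gen <- function(n, seed) {
    set.seed(seed)
    rec <- tibble::tibble(
      mode = rep(c("toxin_sensing", "nutrient_sensing"), length.out = n),
      D = rep(c(1, 3, 5, 7, 9), length.out = n)
    )
    rec$fitness <- rnorm(n, ifelse(rec$mode == "toxin_sensing", 2, 1) -
                           0.05 * rec$D, 0.5)
    rec
  }
  errs <- sapply(c(50, 200, 800), function(n) {
    fit <- fit_fitness_regression(gen(n, seed = 99))
    abs(fit$beta + 0.05)
  })
  expect_lt(errs[3], errs[1])
})

test_that("degenerate regression inputs raise explicit errors", {
  rec <- tibble::tibble(mode = rep("toxin_sensing", 10),
                        D = rep(c(1, 3), 5), fitness = rnorm(10))
  expect_error(fit_fitness_regression(rec), "both type groups")
  rec2 <- tibble::tibble(mode = rep(c("toxin_sensing", "nutrient_sensing"), 5),
                         D = 3, fitness = rnorm(10))
  expect_error(fit_fitness_regression(rec2), "diversity levels")

  # identical fitnesses collapse to beta = 0 and equal intercepts
  rec3 <- tibble::tibble(
    mode = rep(c("toxin_sensing", "nutrient_sensing"), each = 10),
    D = rep(c(1, 3, 5, 7, 9), 4), fitness = 2
  )
  fit <- suppressWarnings(fit_fitness_regression(rec3))  # perfect fit
  expect_equal(fit$beta, 0, tolerance = 1e-10)
  expect_equal(fit$alpha_toxin, fit$alpha_other, tolerance = 1e-10)
  expect_equal(fit$fitness_ratio, 1, tolerance = 1e-10)
})
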