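test_that("derivatives reproduce the hand-evaluated right-hand sides", {
  p <- eco_params()
  d <- derivatives(c(C_A = 0.1, C_B = 0.1, T_A = 0, T_B = 0, N = 1),
                   f_A = 0.3, f_B = 0.1, params = p)
  M <- 1 / 6
  expect_equal(d[["C_A"]], 0.7 * 10 * M * 0.1)
  expect_equal(d[["C_B"]], 0.9 * 10 * M * 0.1)
  expect_equal(d[["T_A"]], 0.3 * M * 0.1)
  expect_equal(d[["N"]], -M * 0.2)

  # N = 0 silences every Monod term; only killing and decay remain
  d0 <- derivatives(c(C_A = 0.2, C_B = 0.1, T_A = 0.05, T_B = 0.02, N = 0),
                    0.3, 0.1, p)
  expect_equal(d0[["C_A"]], -p$k * 0.02 * 0.2)
  expect_equal(d0[["T_A"]], -p$l_T * 0.05)
  expect_equal(d0[["N"]], 0)
})

test_that("zero-investment competition obeys the conservation identity", {
  out <- simulate_competition(0, 0, keep_trajectory = TRUE)
  tot <- conserved_total(out$trajectory, 10)
  expect_lt(max(abs(tot - 10.2)), 1e-6)
})

test_that("conservation holds for arbitrary strategies when k = l_T = 0", {
  p <- eco_params(k = 0, l_T = 0)
  panel <- random_sensing_panel(6, seed = 101)
  for (i in seq(1, 5, by = 2)) {
    out <- simulate_competition(panel[[i]], panel[[i + 1]], p,
                                keep_trajectory = TRUE)
    tot <- conserved_total(out$trajectory, p$mu_max)
    expect_lt(max(abs(tot - tot[1])), 1e-6)
  }
})

test_that("higher constitutive investment wins the asymmetric duel", {
  out <- simulate_competition(strategy_constitutive(0.3),
                              strategy_constitutive(0.1))
  expect_identical(out$local_winner, "A")
  expect_gt(out$final_biomass_A, out$final_biomass_B)
  expect_true(out$extinct_B)
})

test_that("trajectories stay non-negative with non-increasing nutrient", {
  pairs <- random_sensing_panel(8, seed = 202)
  for (i in seq(1, 7, by = 2)) {
    out <- simulate_competition(pairs[[i]], pairs[[i + 1]],
                                keep_trajectory = TRUE)
    tr <- out$trajectory
    expect_true(all(tr$C_A >= 0 & tr$C_B >= 0 & tr$T_A >= 0 &
                      tr$T_B >= 0 & tr$N >= 0))
    expect_true(all(diff(tr$N) <= 1e-12))
  }
})

test_that("swapping strategies and seedings swaps the outcome exactly", {
  sa <- strategy_sensing("toxin_sensing", 0.05, 0.6, 0.02)
  sb <- strategy_constitutive(0.25)
  p <- eco_params(C0_A = 0.12, C0_B = 0.08)
  ps <- eco_params(C0_A = 0.08, C0_B = 0.12)
  o1 <- simulate_competition(sa, sb, p)
  o2 <- simulate_competition(sb, sa, ps)
  expect_identical(o1$final_biomass_A, o2$final_biomass_B)
  expect_identical(o1$final_biomass_B, o2$final_biomass_A)
  expect_identical(o1$extinct_A, o2$extinct_B)
})

test_that("identical strategies with equal seeding stay symmetric", {
  out <- simulate_competition(0.35, 0.35, keep_trajectory = TRUE)
  expect_identical(out$trajectory$C_A, out$trajectory$C_B)
  expect_identical(out$local_winner, "tie")
})

test_that("repeated runs are bit-identical", {
  s <- strategy_sensing("quorum_sensing", 0.1, 0.6, 0.3)
  o1 <- simulate_competition(s, 0.2, keep_trajectory = TRUE)
  o2 <- simulate_competition(s, 0.2, keep_trajectory = TRUE)
  expect_identical(o1$final_biomass_A, o2$final_biomass_A)
  expect_identical(o1$trajectory, o2$trajectory)
})

test_that("implicit Euler converges first order toward the reference", {
  dev1 <- validate_against_reference(0.3, 0.1)$max_relative_deviation
  dev2 <- validate_against_reference(0.3, 0.1,
                                     eco_params(dt = 0.005))$max_relative_deviation
  expect_lt(dev2, dev1)
  # halving the step should roughly halve the error for a first-order scheme
  expect_lt(dev2, 0.75 * dev1)
})

test_that("refined integration matches the adaptive reference closely", {
  v <- validate_against_reference(strategy_constitutive(0.2),
                                  strategy_constitutive(0.25),
                                  substeps = 100)
  expect_lt(v$max_relative_deviation, 1e-3)
})

test_that("extinct strains are removed while their toxin keeps decaying", {
  out <- simulate_competition(0.5, 0, eco_params(k = 40),
                              keep_trajectory = TRUE)
  expect_true(out$extinct_B)
  tr <- out$trajectory
  i_ext <- which(tr$C_B == 0)[1]
  expect_true(all(tr$C_B[i_ext:nrow(tr)] == 0))
  # strain B produced nothing (f_B = 0); strain A's toxin decays after
  # nutrient exhaustion instead of being zeroed
  expect_true(all(diff(tr$T_A[seq(nrow(tr) - 100, nrow(tr))]) <= 0))
})
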