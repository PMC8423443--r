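test_that("invasion index matches direct recomputation from two competitions", {
  inv <- strategy_constitutive(0.3)
  res <- strategy_constitutive(0.1)
  r <- invasion_index(inv, res)
  w_res <- simulate_competition(res, res)$final_biomass_A
  mixed <- simulate_competition(inv, res)
  expect_identical(r$w_res, w_res)
  expect_identical(r$w_inv, mixed$final_biomass_A)
  expect_identical(r$I_inv, mixed$final_biomass_A / w_res)
})

test_that("self-invasion is neutral", {
  r <- invasion_index(0.25, 0.25)
  expect_equal(r$I_inv, 1, tolerance = 1e-12)
  expect_identical(r$local_winner, "tie")
  expect_identical(stable_invasion(0.25, 0.25)$verdict, "no_invasion")
})

test_that("outcome classification distinguishes local and global results", {
  expect_identical(toxwar:::classify_outcome(1.5, "A"), "win_local_win_global")
  expect_identical(toxwar:::classify_outcome(0.5, "B"), "lose_local_lose_global")
  expect_identical(toxwar:::classify_outcome(0.5, "A"), "win_local_lose_global")
  expect_identical(toxwar:::classify_outcome(1.5, "B"), "lose_local_win_global")
  expect_identical(toxwar:::classify_outcome(1, "A"), "mixed")
  expect_identical(toxwar:::classify_outcome(1.4, "tie"), "mixed")

  # an aggressive winner that makes few cells loses globally
  expect_identical(invasion_index(0.35, 0)$outcome_class,
                   "win_local_lose_global")
})

test_that("PIP matrix equals brute force over all pairs and has unit diagonal", {
  g <- c(0.1, 0.3, 0.5)
  pip <- pairwise_invasibility(g)
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      expect_equal(pip$I[i, j], invasion_index(g[i], g[j])$I_inv,
                   tolerance = 1e-12)
    }
  }
  expect_true(all(abs(diag(pip$I) - 1) < 1e-9))
})

test_that("pairwise_invasibility validates its grid", {
  expect_error(pairwise_invasibility(c(0.5)), "sorted")
  expect_error(pairwise_invasibility(c(0.5, 0.1)), "sorted")
  expect_error(pairwise_invasibility(c(0.1, 1.5)), "sorted")
})

test_that("harmless toxins select zero investment", {
  e <- find_ess(eco_params(k = 0), grid_step = 0.05)
  expect_equal(e$f_star, 0)
})

test_that("coarse and fine ESS searches agree to grid resolution", {
  e5 <- find_ess(grid_step = 0.05)
  e1 <- find_ess(grid_step = 0.01)
  expect_false(is.na(e5$f_star))
  expect_false(is.na(e1$f_star))
  expect_lte(abs(e5$f_star - e1$f_star), 0.05)
})

test_that("the reported ESS certificate is verified against the grid", {
  e <- find_ess(grid_step = 0.05)
  pip <- e$pip
  i <- which(pip$f_grid == e$f_star)
  others <- setdiff(seq_along(pip$f_grid), i)
  # nothing invades the reported strategy
  expect_false(any(pip$I[others, i] > 1 + 1e-6, na.rm = TRUE))
  # and it invades at least every strategy that is invadable at all
  invadable <- sapply(others, function(j) {
    any(pip$I[setdiff(seq_along(pip$f_grid), j), j] > 1 + 1e-6, na.rm = TRUE)
  })
  expect_true(all(pip$I[i, others][invadable] > 1 + 1e-6))
})

test_that("faster-killing toxins raise the ESS and arm it against pacifists", {
  fast <- eco_params(k = 40)
  e <- find_ess(fast, grid_step = 0.05)
  # with a doubled kill rate the non-producer is no longer a safe corner:
  # the optimum passes the strict invades-all certificate and sits higher
  expect_true(e$strict)
  expect_equal(e$f_star, 0.35, tolerance = 0.05)
  expect_gt(e$f_star, find_ess(grid_step = 0.05)$f_star)
  expect_gt(invasion_index(0.15, 0, fast)$I_inv, 1)
})

test_that("stable invasion partitions into the three verdicts", {
  # attack-then-disarm nutrient sensor displaces the constitutive optimum
  s <- strategy_sensing("nutrient_sensing", 0.35, 0, 0.5)
  v <- stable_invasion(s, strategy_constitutive(0.35))
  expect_identical(v$verdict, "invades_stably")
  expect_gt(v$I_forward, 1)
  expect_lte(v$I_backward, 1 + 1e-6)
})
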