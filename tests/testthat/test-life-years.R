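test_that("expected life-years lost is probability times years", {
  expect_equal(expected_life_years_lost(1 / 570, 83), 83 / 570)
  expect_equal(round(expected_life_years_lost(1 / 570, 83), 4), 0.1456)
  expect_equal(expected_life_years_lost(0, 83), 0)
  expect_equal(expected_life_years_lost(0.3, 0), 0)
})

test_that("degenerate inputs reproduce the closed-form break-even", {
  # fixed HDFN risk 1/570, 83 years lost, 40 survivor life-years:
  # break-even s* = 100 * (83/570) / 40 = 0.3640%
  grid <- seq(0, 2, by = 0.005)
  tr <- tradeoff_bootstrap(rep(1 / 570, 50), dist_point(40),
                           years_per_event = 83, benefit_grid = grid,
                           bootstrap_samples = 2000, seed = 1)
  s_star <- 100 * (83 / 570) / 40
  expect_equal(tr$break_even_benefit, grid[which(grid >= s_star)[1]])
  expect_true(tr$reached)
  # probabilities are a step function around s*
  probs <- tidy(tr)
  expect_true(all(probs$prob_gain_exceeds_loss[grid < s_star - 0.005] == 0))
  expect_true(all(probs$prob_gain_exceeds_loss[grid >= s_star] == 1))
})

test_that("limiting cases: no HDFN risk, and nothing to gain", {
  grid <- seq(0, 1, by = 0.1)
  none <- tradeoff_bootstrap(rep(0, 20), dist_point(40),
                             benefit_grid = grid, bootstrap_samples = 500)
  expect_equal(none$break_even_benefit, 0)
  expect_true(all(tidy(none)$prob_gain_exceeds_loss == 1))

  nothing <- tradeoff_bootstrap(rep(1 / 570, 20), dist_point(0),
                                benefit_grid = grid,
                                bootstrap_samples = 500)
  expect_false(nothing$reached)
  expect_true(is.na(nothing$break_even_benefit))
})

test_that("probability is monotone along the grid and the bootstrap is seeded", {
  sc <- study_shaped_scenario(13)
  risk <- run_simulation(sc$config, "dneg_females_cbp", iterations = 1000)
  grid <- seq(0.05, 3, by = 0.05)
  tr1 <- tradeoff_bootstrap(risk$samples[, "hdfn"], dist_uniform(20, 60),
                            benefit_grid = grid, bootstrap_samples = 5000,
                            seed = 4)
  tr2 <- tradeoff_bootstrap(risk$samples[, "hdfn"], dist_uniform(20, 60),
                            benefit_grid = grid, bootstrap_samples = 5000,
                            seed = 4)
  expect_identical(tr1$grid, tr2$grid)
  expect_true(all(diff(tidy(tr1)$prob_gain_exceeds_loss) >= 0))
})

test_that("break-even moves with risk and with survivor life-years", {
  grid <- seq(0.01, 5, by = 0.01)
  be <- function(p, ly) {
    tradeoff_bootstrap(rep(p, 10), dist_point(ly), benefit_grid = grid,
                       bootstrap_samples = 200)$break_even_benefit
  }
  # non-decreasing in HDFN risk
  expect_true(be(1 / 2000, 40) <= be(1 / 570, 40))
  expect_true(be(1 / 570, 40) <= be(1 / 200, 40))
  # non-increasing in survivor life-years
  expect_true(be(1 / 570, 60) <= be(1 / 570, 30))
})
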