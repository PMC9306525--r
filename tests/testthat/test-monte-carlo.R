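test_that("point-mass inputs reproduce the analytic chain product exactly", {
  cfg <- make_chain_config(list(dist_point(0.5), dist_point(0.2),
                                dist_point(0.1)))
  risk <- run_simulation(cfg, "all_recipients", iterations = 200)
  est <- tidy(risk)
  analytic <- chain_probability(cfg, "harm1")
  expect_identical(unique(risk$samples[, "harm1"]), analytic)
  h <- est[est$harm_id == "harm1", ]
  expect_identical(h$mean_probability, analytic)
  expect_identical(h$ci_low_probability, h$ci_high_probability)
  expect_identical(h$reciprocal_mean, 1 / analytic)
})

test_that("a single uniform(0,1) event recovers closed-form mean and CI", {
  cfg <- make_chain_config(list(dist_uniform(0, 1)))
  risk <- run_simulation(cfg, "all_recipients", iterations = 1e5, seed = 5)
  h <- tidy(risk)[1, ]
  se <- sqrt(1 / 12 / 1e5)
  expect_lt(abs(h$mean_probability - 0.5), 3 * se)
  expect_lt(abs(h$ci_low_probability - 0.025), 0.005)
  expect_lt(abs(h$ci_high_probability - 0.975), 0.005)
})

test_that("the same seed gives bit-identical results", {
  cfg <- default_config()
  r1 <- run_simulation(cfg, "dneg_females_cbp", seed = 42)
  r2 <- run_simulation(cfg, "dneg_females_cbp", seed = 42)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$estimates, r2$estimates)
  r3 <- run_simulation(cfg, "dneg_females_cbp", seed = 43)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("re-typing one input leaves the other inputs' draws unchanged", {
  cfg <- default_config()
  before <- scatter_pairs(cfg, "all_recipients", "N6", iterations = 500,
                          seed = 9)
  # change N3's family entirely; N6's substream must not move
  cfg$inputs$dist[[match("N3", cfg$inputs$input_id)]] <- dist_beta(2, 300)
  after <- scatter_pairs(cfg, "all_recipients", "N6", iterations = 500,
                         seed = 9)
  expect_identical(before$input_value, after$input_value)
})

test_that("credibility intervals match a sort-based quantile oracle", {
  set.seed(31)
  cases <- list(
    1:1000,
    stats::rlnorm(507, -9, 1),
    stats::runif(64),
    c(rep(0, 10), stats::runif(90, 0, 1e-4))
  )
  for (x in cases) {
    for (level in c(0.5, 0.9, 0.95, 0.99)) {
      expect_equal(credibility_interval(x, level),
                   oracle_interval(x, level), tolerance = 1e-12)
    }
  }
  expect_equal(credibility_interval(rep(3.3, 8), 0.95), c(3.3, 3.3))
  med <- stats::median(cases[[2]])
  expect_equal(credibility_interval(cases[[2]], 0), c(med, med))
  expect_error(credibility_interval(numeric(0)), "non-empty")
  expect_error(credibility_interval(1:5, 1), "level")
})

test_that("reciprocal reporting and its display rounding", {
  expect_equal(to_reciprocal(0.002), 500)
  expect_equal(to_reciprocal(1), 1)
  expect_identical(to_reciprocal(0), Inf)
  expect_error(to_reciprocal(-0.1))
  # reciprocal-sum of the three all-recipient harm risks, 2 s.f.
  p <- 1 / 27000 + 1 / 850000 + 1 / 29000
  expect_equal(signif(to_reciprocal(p), 2), 1.4e4)
  expect_equal(format_reciprocal(0.002), "1 in 500")
  expect_equal(format_reciprocal(0), "no events expected")
})

test_that("reciprocal CI endpoints are sorted and consistent", {
  sc <- study_shaped_scenario(3)
  for (pop in c("all_recipients", "dneg_females_cbp")) {
    est <- tidy(run_simulation(sc$config, pop, iterations = 400))
    expect_true(all(est$ci_low_probability <= est$ci_high_probability))
    expect_true(all(est$reciprocal_lo <= est$reciprocal_hi))
    expect_equal(est$reciprocal_lo, 1 / est$ci_high_probability)
    expect_equal(est$reciprocal_hi, 1 / est$ci_low_probability)
    expect_equal(est$reciprocal_mean, 1 / est$mean_probability)
  }
})

test_that("Monte Carlo means converge to the product of input means", {
  cfg <- make_chain_config(list(dist_uniform(0.1, 0.3),
                                dist_beta(3, 7),
                                dist_triangular(0.2, 0.5, 0.8)))
  sc <- dposrisk:::scenario_truth(cfg)
  truth <- sc$truth[sc$truth$harm_id == "harm1", ]
  risk <- run_simulation(cfg, "all_recipients", iterations = 1e5, seed = 2)
  se <- sqrt(truth$analytic_var / 1e5)
  expect_lt(abs(tidy(risk)$mean_probability[1] - truth$analytic_mean),
            4 * se)
})
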