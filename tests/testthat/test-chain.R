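test_that("chain probability is the product of per-event probabilities", {
  cfg <- make_chain_config(list(dist_point(0.5), dist_point(0.2),
                                dist_point(0.1)))
  expect_equal(chain_probability(cfg, "harm1"), 0.01)
  expect_equal(
    chain_probability(cfg, "harm1",
                      fixed_probabilities = c(X1 = 1, X2 = 1, X3 = 1)),
    1
  )
  expect_equal(
    chain_probability(cfg, "harm1", fixed_probabilities = c(X2 = 0)),
    0
  )
  expect_error(
    chain_probability(cfg, "harm1", fixed_probabilities = c(X2 = 1.5)),
    "X2"
  )
  expect_error(chain_probability(cfg, "nope"), "nope")
})

test_that("increasing one event probability never decreases any harm", {
  sc <- study_shaped_scenario(11)
  cfg <- sc$config
  for (ev in c("X1", "X2", "X6", "X12")) {
    base <- sapply(cfg$harms$harm_id, function(h) {
      chain_probability(cfg, h, population_id = "all_recipients")
    })
    chains <- cfg$harms$chain
    names(chains) <- cfg$harms$harm_id
    for (delta in c(0.05, 0.2)) {
      row <- match(cfg$events$input_ref[cfg$events$event_id == ev],
                   cfg$inputs$input_id)
      old_mean <- dist_mean(cfg$inputs$dist[[row]])
      up <- conditional_fix(cfg, cfg$inputs$input_id[row],
                            min(1, old_mean + delta))
      bumped <- sapply(up$harms$harm_id, function(h) {
        chain_probability(up, h, population_id = "all_recipients")
      })
      expect_true(all(bumped >= base - 1e-15))
    }
  }
})

test_that("combined risk is additive, capped, and close to the exact union", {
  expect_equal(combined_risk(c(0, 0, 0)), 0)
  expect_equal(combined_risk(c(0.6, 0.7)), 1)
  expect_gte(combined_risk(c(0.01, 0.002, 0.5)), 0.5)
  expect_error(combined_risk(numeric(0)), "non-empty")
  expect_error(combined_risk(c(0.2, 1.3)))

  # at per-transfusion risk scales the additive and union forms agree
  set.seed(42)
  for (i in 1:50) {
    p <- stats::runif(3, 0, 2e-3)
    expect_lt(abs(combined_risk(p) - combined_risk(p, method = "union")),
              1e-5)
  }
})

test_that("policy mix scales risk linearly and composes multiplicatively", {
  expect_equal(apply_policy_mix(0.002, 1), 0.002)
  expect_equal(apply_policy_mix(0.002, 0), 0)
  expect_equal(apply_policy_mix(0.002, 0.5), 0.001)
  p <- c(0.1, 0.02, 0.003)
  expect_equal(apply_policy_mix(apply_policy_mix(p, 0.5), 0.4),
               apply_policy_mix(p, 0.2))
  expect_error(apply_policy_mix(0.1, 1.5), "dpos_fraction")
})

test_that("conditional_fix replaces exactly one input with a point mass", {
  cfg <- make_chain_config(list(dist_uniform(0.1, 0.3), dist_point(0.4)))
  fixed <- conditional_fix(cfg, "N1", 0.1)
  expect_equal(fixed$inputs$dist[[1]]$family, "point")
  expect_equal(fixed$inputs$dist[[1]]$params$p, 0.1)
  expect_equal(fixed$inputs$dist[[2]], cfg$inputs$dist[[2]])
  expect_equal(chain_probability(fixed, "harm1"), 0.1 * 0.4)

  # fixing at zero zeroes every downstream harm
  zeroed <- conditional_fix(cfg, "N1", 0)
  expect_equal(chain_probability(zeroed, "harm1"), 0)
  risk <- run_simulation(zeroed, "all_recipients", iterations = 50)
  expect_true(all(risk$samples[, "harm1"] == 0))

  # fixing a point input at its current value is a no-op for results
  same <- conditional_fix(cfg, "N2", 0.4)
  expect_identical(
    run_simulation(same, "all_recipients", iterations = 100)$estimates,
    run_simulation(cfg, "all_recipients", iterations = 100)$estimates
  )
  expect_error(conditional_fix(cfg, "N99", 0.1), "N99")
})
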