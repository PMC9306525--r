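test_that("scenario generation is deterministic and hits its risk scale", {
  s1 <- generate_scenario(2, n_events = 5, target_risk_scale = 1e-4)
  s2 <- generate_scenario(2, n_events = 5, target_risk_scale = 1e-4)
  expect_equal(s1, s2)
  truth <- s1$truth[s1$truth$harm_id == "harm1", ]
  expect_lt(abs(log10(truth$analytic_mean) - log10(1e-4)), 0.5)
  expect_error(generate_scenario(1, target_risk_scale = 0), "\\(0, 1\\]")
})

test_that("point-only scenarios have exactly analytic product truth", {
  sc <- generate_scenario(1, n_events = 3, families = "point",
                          target_risk_scale = 1e-3)
  means <- purrr::map_dbl(sc$config$inputs$dist, dist_mean)
  truth <- sc$truth[sc$truth$harm_id == "harm1", ]
  expect_identical(truth$analytic_mean, prod(means))
  risk <- run_simulation(sc$config, "all_recipients", iterations = 10)
  expect_identical(unique(risk$samples[, "harm1"]), prod(means))
})

test_that("Monte Carlo means recover analytic truth across 20 scenarios", {
  n_iter <- 1e5
  set.seed(123)
  hits <- vapply(1:20, function(s) {
    sc <- generate_scenario(s, n_events = 14,
                            target_risk_scale = 10^stats::runif(1, -5, -3))
    truth <- sc$truth[sc$truth$harm_id == "harm1" &
                        sc$truth$population_id == "all_recipients", ]
    risk <- run_simulation(sc$config, "all_recipients",
                           iterations = n_iter, seed = s + 1000)
    se <- sqrt(truth$analytic_var / n_iter)
    abs(tidy(risk)$mean_probability[1] - truth$analytic_mean) <
      max(4 * se, 1e-15)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("the study-shaped scenario has the expected structure and truth", {
  sc <- study_shaped_scenario(7)
  expect_equal(sc, study_shaped_scenario(7))
  cfg <- sc$config
  expect_equal(nrow(cfg$events), 14)
  expect_equal(nrow(cfg$harms), 3)
  expect_setequal(cfg$populations$population_id,
                  c("all_recipients", "dneg_females_cbp"))

  truth <- sc$truth
  all_rec <- truth[truth$population_id == "all_recipients", ]
  # reciprocal risks land near the intended orders of magnitude
  expect_lt(abs(log10(all_rec$analytic_reciprocal[
    all_rec$harm_id == "htr_index"]) - log10(2.7e4)), 0.5)
  expect_lt(abs(log10(all_rec$analytic_reciprocal[
    all_rec$harm_id == "htr_future"]) - log10(8.5e5)), 0.5)
  expect_lt(abs(log10(all_rec$analytic_reciprocal[
    all_rec$harm_id == "hdfn"]) - log10(2.9e4)), 0.5)

  # combined risk dominates every component
  for (pop in unique(truth$population_id)) {
    tp <- truth[truth$population_id == pop, ]
    expect_gte(tp$analytic_mean[tp$harm_id == "any_harm"],
               max(tp$analytic_mean[tp$harm_id != "any_harm"]))
  }
  # the subgroup's overrides remove sub-unit factors, raising HDFN risk
  expect_gt(truth$analytic_mean[truth$harm_id == "hdfn" &
                                  truth$population_id == "dneg_females_cbp"],
            truth$analytic_mean[truth$harm_id == "hdfn" &
                                  truth$population_id == "all_recipients"])

  # end-to-end run produces 3 + 1 estimates per population
  for (pop in cfg$populations$population_id) {
    est <- tidy(run_simulation(cfg, pop, iterations = 200))
    expect_equal(nrow(est), 4)
    expect_true("any_harm" %in% est$harm_id)
  }
})

test_that("scenario configs survive the config file round trip", {
  sc <- study_shaped_scenario(9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(sc$config, path)
  reloaded <- load_config(path)
  expect_equal(reloaded, sc$config, tolerance = 1e-12)
  # identical draws after reload
  expect_identical(
    run_simulation(reloaded, "all_recipients", iterations = 100)$samples,
    run_simulation(sc$config, "all_recipients", iterations = 100)$samples
  )
})
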