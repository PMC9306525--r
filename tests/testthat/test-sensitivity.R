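test_that("pick-freeze recovers closed-form indices for a linear model", {
  # Y = X1 + 2*X2, X1, X2 ~ U(0,1): Var = 5/12, S1 = 0.2, S2 = 0.8
  model <- function(X) X[, "x1"] + 2 * X[, "x2"]
  samplers <- list(x1 = dist_uniform(0, 1), x2 = dist_uniform(0, 1))
  reps <- purrr::map_dfr(1:10, function(s) {
    sobol_first_order(model, samplers, n = 4096, seed = s)
  })
  s1 <- reps$s_index[reps$input_id == "x1"]
  s2 <- reps$s_index[reps$input_id == "x2"]
  expect_lt(abs(mean(s1) - 0.2), 3 * stats::sd(s1))
  expect_lt(abs(mean(s2) - 0.8), 3 * stats::sd(s2))
  expect_lt(abs(mean(s1 + s2) - 1), 3 * stats::sd(s1 + s2))
})

test_that("pick-freeze agrees with the double-loop oracle on a product model", {
  # Y = X1 * X2 with asymmetric input uncertainty
  f <- function(x1, x2) x1 * x2
  model <- function(X) X[, "x1"] * X[, "x2"]
  samplers <- list(x1 = dist_uniform(0.1, 0.5), x2 = dist_beta(2, 5))
  set.seed(77)
  oracle1 <- oracle_sobol_2in(f, function(n) stats::runif(n, 0.1, 0.5),
                              function(n) stats::rbeta(n, 2, 5), which = 1)
  oracle2 <- oracle_sobol_2in(f, function(n) stats::rbeta(n, 2, 5),
                              function(n) stats::runif(n, 0.1, 0.5),
                              which = 2)
  reps <- purrr::map_dfr(1:10, function(s) {
    sobol_first_order(model, samplers, n = 4096, seed = s)
  })
  s1 <- reps$s_index[reps$input_id == "x1"]
  s2 <- reps$s_index[reps$input_id == "x2"]
  expect_lt(abs(mean(s1) - oracle1), 3 * max(stats::sd(s1), 0.02))
  expect_lt(abs(mean(s2) - oracle2), 3 * max(stats::sd(s2), 0.02))
})

test_that("degenerate attributions: point mass gives 0, sole driver gives 1", {
  model <- function(X) X[, "a"] * X[, "b"]
  res <- sobol_first_order(
    model,
    list(a = dist_point(0.3), b = dist_uniform(0.1, 0.9)),
    n = 4096, seed = 2
  )
  expect_lt(abs(res$s_index[res$input_id == "a"]), 0.02)
  expect_lt(abs(res$s_index[res$input_id == "b"] - 1), 0.05)

  # all inputs fixed: zero output variance is defined as index 0
  expect_warning(
    zero <- sobol_first_order(
      model, list(a = dist_point(0.3), b = dist_point(0.5)),
      n = 256, seed = 1
    ),
    "variance"
  )
  expect_equal(zero$s_index, c(0, 0))
})

test_that("indices of the multiplicative chain model sum to at most ~1", {
  sc <- study_shaped_scenario(21)
  sens <- sensitivity_indices(sc$config, "dneg_females_cbp",
                              harm_id = "hdfn", n = 4096, seed = 3)
  expect_true(all(is.finite(tidy(sens)$s_index)))
  expect_lte(sum(tidy(sens)$s_index), 1.1)
  # the overridden events are constants in this population
  overridden <- grepl("@dneg_females_cbp", tidy(sens)$input_id)
  expect_true(all(abs(tidy(sens)$s_index[overridden]) < 1e-12))
})

test_that("scatter export aligns with the simulation draws", {
  cfg <- default_config()
  pairs1 <- scatter_pairs(cfg, "all_recipients", "N6", harm_id = "hdfn",
                          iterations = 300, seed = 8)
  pairs2 <- scatter_pairs(cfg, "all_recipients", "N6", harm_id = "hdfn",
                          iterations = 300, seed = 8)
  expect_identical(pairs1, pairs2)
  risk <- run_simulation(cfg, "all_recipients", iterations = 300, seed = 8)
  expect_identical(pairs1$output_value, unname(risk$samples[, "hdfn"]))

  # single-event chain: the scatter lies exactly on the identity line
  single <- make_chain_config(list(dist_uniform(0, 1)))
  pr <- scatter_pairs(single, "all_recipients", "N1", harm_id = "harm1",
                      iterations = 100, seed = 1)
  expect_identical(pr$input_value, pr$output_value)

  # point-mass input: all abscissae equal
  pm <- make_chain_config(list(dist_point(0.25), dist_uniform(0, 1)))
  pp <- scatter_pairs(pm, "all_recipients", "N1", harm_id = "harm1",
                      iterations = 50)
  expect_equal(unique(pp$input_value), 0.25)
  expect_error(scatter_pairs(pm, "all_recipients", "N99"), "N99")
})
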