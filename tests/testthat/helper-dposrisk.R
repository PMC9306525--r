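# Shared fixtures and independent oracles.

# internal RNG helpers, exercised directly by the determinism tests
with_stream <- dposrisk:::with_stream
draw_stream_for_test <- dposrisk:::draw_stream
`%||%` <- rlang::`%||%`

# Minimal single-population config: one event per supplied distribution,
# one harm chaining them all in order.
make_chain_config <- function(dists, mc = list(), life_years = NULL) {
  n <- length(dists)
  ids <- paste0("N", seq_len(n))
  ev <- paste0("X", seq_len(n))
  model_config(
    inputs = tibble::tibble(input_id = ids, dist = unname(dists)),
    events = tibble::tibble(event_id = ev, label = ev, input_ref = ids,
                            overrides = vector("list", n)),
    harms = tibble::tibble(harm_id = "harm1", label = "harm",
                           chain = list(ev)),
    populations = tibble::tibble(
      population_id = "all_recipients", label = "all",
      incidence_per_million_per_year = 83, population_size = 67e6,
      subgroup_fraction = 1
    ),
    mc = mc, life_years = life_years
  )
}

# Sort-based equal-tailed quantile oracle: explicit type-7 interpolation
# between order statistics, written independently of stats::quantile().
oracle_interval <- function(x, level) {
  xs <- sort(x)
  n <- length(xs)
  at <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  a <- (1 - level) / 2
  c(at(a), at(1 - a))
}

# Brute-force double-loop conditional-variance Sobol oracle for a model
# y = f(x1, x2): outer loop over fixed values of the target input, inner
# Monte Carlo over the other input.
oracle_sobol_2in <- function(f, r_target, r_other, which = 1,
                             outer_n = 300, inner_n = 2000) {
  fixed <- r_target(outer_n)
  cond_means <- vapply(fixed, function(v) {
    other <- r_other(inner_n)
    if (which == 1) mean(f(rep(v, inner_n), other))
    else mean(f(other, rep(v, inner_n)))
  }, numeric(1))
  big1 <- r_target(outer_n * inner_n)
  big2 <- r_other(outer_n * inner_n)
  y <- if (which == 1) f(big1, big2) else f(big2, big1)
  stats::var(cond_means) / stats::var(y)
}
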