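# Synthetic scenario generator: configurations with closed-form ground
# truth (input moments, analytic harm probabilities) for parameter-recovery
# and end-to-end testing.

#' Generate a synthetic scenario with analytic ground truth
#'
#' Builds a random single-harm chain of `n_events` events whose input
#' distributions are drawn from the requested families with admissible
#' random parameters, scaled so that the analytic harm probability (the
#' product of the input means, exact under input independence) is close to
#' `target_risk_scale`. The closed-form mean and variance of every input,
#' and of the harm probability, are recorded so Monte Carlo output can be
#' checked against exact truth.
#'
#' @param seed Seed; the same seed reproduces the scenario exactly.
#' @param n_events Number of chain events (>= 1).
#' @param families Distribution families to draw from (subset of
#'   `point`, `uniform`, `triangular`, `beta`, `log_uniform`).
#' @param target_risk_scale Desired analytic harm probability, in (0, 1\].
#' @return An object of class `dpr_scenario`: `config` (a `dpr_config`),
#'   `truth` (tibble of analytic mean, variance and reciprocal per harm and
#'   population) and `input_moments` (closed-form mean and variance per
#'   input).
#' @examples
#' sc <- generate_scenario(1, n_events = 3, families = "point",
#'                         target_risk_scale = 1e-3)
#' sc$truth
#' @export
generate_scenario <- function(seed, n_events = 5,
                              families = DIST_FAMILIES,
                              target_risk_scale = 1e-4) {
  stopifnot(n_events >= 1)
  if (is.na(target_risk_scale) || target_risk_scale <= 0 ||
      target_risk_scale > 1) {
    stop("target_risk_scale must lie in (0, 1]", call. = FALSE)
  }
  families <- match.arg(families, DIST_FAMILIES, several.ok = TRUE)

  built <- with_stream(substream_seed(seed, "scenario"), function() {
    base <- target_risk_scale^(1 / n_events)
    means <- pmin(0.95, pmax(1e-6, base * exp(stats::runif(n_events,
                                                           -0.3, 0.3))))
    # re-anchor the last event so the product hits the target when feasible
    if (n_events > 1) {
      rest <- prod(means[-n_events])
      means[n_events] <- pmin(0.95, pmax(1e-6, target_risk_scale / rest))
    }
    fams <- sample(families, n_events, replace = TRUE)
    dists <- purrr::map2(means, fams, random_dist_with_mean)
    list(means = means, dists = dists)
  })

  ids <- paste0("N", seq_len(n_events))
  ev_ids <- paste0("X", seq_len(n_events))
  inputs <- tibble::tibble(input_id = ids, dist = built$dists)
  events <- tibble::tibble(
    event_id = ev_ids,
    label = paste("synthetic event", seq_len(n_events)),
    input_ref = ids,
    overrides = vector("list", n_events)
  )
  harms <- tibble::tibble(harm_id = "harm1", label = "synthetic harm",
                          chain = list(ev_ids))
  populations <- tibble::tibble(
    population_id = "all_recipients",
    label = "all recipients",
    incidence_per_million_per_year = 83,
    population_size = 67e6,
    subgroup_fraction = 1
  )
  config <- model_config(inputs, events, harms, populations,
                         mc = list(seed = seed))
  scenario_truth(config)
}

# A random admissible distribution of the given family with exact mean m.
random_dist_with_mean <- function(m, family) {
  switch(family,
    point = dist_point(m),
    uniform = {
      w <- min(m, 1 - m) * stats::runif(1, 0.2, 0.9)
      dist_uniform(m - w, m + w)
    },
    triangular = {
      w <- min(m, 1 - m) * stats::runif(1, 0.2, 0.9)
      dist_triangular(m - w, m, m + w)
    },
    beta = {
      conc <- stats::runif(1, 5, 50)
      dist_beta(m * conc, (1 - m) * conc)
    },
    log_uniform = {
      # mean of log-uniform(a, rho * a) is a (rho - 1) / log(rho)
      rho <- exp(stats::runif(1, 0.5, 2))
      a <- m * log(rho) / (rho - 1)
      if (rho * a > 1) {
        dist_uniform(max(0, 2 * m - 1), 1) # mean m near the upper edge
      } else {
        dist_log_uniform(a, rho * a)
      }
    }
  )
}

# Closed-form truth tables for any configuration.
scenario_truth <- function(config) {
  input_moments <- tibble::tibble(
    input_id = config$inputs$input_id,
    mean = purrr::map_dbl(config$inputs$dist, dist_mean),
    var = purrr::map_dbl(config$inputs$dist, dist_var)
  )
  grid <- tidyr::expand_grid(
    harm_id = config$harms$harm_id,
    population_id = config$populations$population_id
  )
  truth <- purrr::pmap_dfr(grid, function(harm_id, population_id) {
    chain <- harm_chain(config, harm_id)
    dists <- lapply(chain, function(ev) {
      event_dist(config, ev, population_id)
    })
    # draws of events sharing one input are identical within an iteration,
    # so moments of the product must respect that coupling; chains in this
    # package reference each input once per chain, which validate() of the
    # generator guarantees
    means <- vapply(dists, dist_mean, numeric(1))
    m2 <- vapply(dists, function(d) dist_var(d) + dist_mean(d)^2,
                 numeric(1))
    mu <- prod(means)
    tibble::tibble(
      harm_id = harm_id,
      population_id = population_id,
      analytic_mean = mu,
      analytic_var = prod(m2) - mu^2,
      analytic_reciprocal = ifelse(mu > 0, 1 / mu, Inf)
    )
  })
  any_rows <- truth |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(
      harm_id = "any_harm",
      analytic_mean = min(1, sum(.data$analytic_mean)),
      analytic_var = NA_real_,
      analytic_reciprocal = 1 / min(1, sum(.data$analytic_mean)),
      .groups = "drop"
    )
  structure(
    list(
      config = config,
      truth = dplyr::bind_rows(truth, any_rows),
      input_moments = input_moments
    ),
    class = "dpr_scenario"
  )
}

#' @export
print.dpr_scenario <- function(x, ...) {
  cat("<dpr_scenario> ", nrow(x$config$events), " events, ",
      nrow(x$config$harms), " harms, ", nrow(x$config$populations),
      " populations\n", sep = "")
  print(x$truth)
  invisible(x)
}

#' Synthetic scenario with the full study structure
#'
#' Builds a 14-event, 3-harm, 2-population scenario with the same shape as
#' the prehospital D-positive transfusion model: an index haemolytic
#' transfusion reaction chain, a future-HTR chain and an HDFN chain
#' sharing the common prefix (recipient is D-negative, survives the index
#' event) and, for the latter two, the alloimmunization event. The
#' D-negative females of childbearing potential population fixes the
#' D-negative and female-CBP events at probability 1 via overrides. Input
#' parameters are randomized admissibly and scaled so the three analytic
#' all-recipient reciprocal risks land near 3 x 10^4, 9 x 10^5 and
#' 3 x 10^4 transfusions per event — the order-of-magnitude regime of a
#' realistic national risk assessment, so end-to-end tests exercise the
#' small-probability arithmetic the model lives in.
#'
#' @param seed Seed; the same seed reproduces the scenario exactly.
#' @return A `dpr_scenario` (see [generate_scenario()]).
#' @examples
#' sc <- study_shaped_scenario(7)
#' sc$truth
#' @export
study_shaped_scenario <- function(seed) {
  chains <- list(
    htr_index = c("X1", "X2", "X3", "X4", "X5"),
    htr_future = c("X1", "X2", "X6", "X7", "X8", "X9", "X10"),
    hdfn = c("X1", "X2", "X6", "X11", "X12", "X13", "X14")
  )
  targets <- c(htr_index = 1 / 2.7e4, htr_future = 1 / 8.5e5,
               hdfn = 1 / 2.9e4)
  labels <- c(
    X1 = "Recipient is D-negative",
    X2 = "Recipient survives index event",
    X3 = "Recipient has pre-existing anti-D",
    X4 = "HTR given anti-D and D-positive transfusion",
    X5 = "Major morbidity or death given index HTR",
    X6 = "D-alloimmunization after index transfusion",
    X7 = "Recipient receives a future transfusion",
    X8 = "Future transfusion is D-positive",
    X9 = "HTR at future transfusion",
    X10 = "Major morbidity or death given future HTR",
    X11 = "Recipient is a female of childbearing potential",
    X12 = "Future pregnancy occurs",
    X13 = "Foetus is D-positive",
    X14 = "Foetal death or disability given HDFN"
  )

  built <- with_stream(substream_seed(seed, "study_shaped"), function() {
    jit <- function(n, lo = -0.15, hi = 0.15) exp(stats::runif(n, lo, hi))
    means <- c(X1 = 0.15, X2 = 0.70, X6 = 0.25) * jit(3)
    for (h in names(chains)) {
      tail_ids <- setdiff(chains[[h]], names(means))
      prefix <- prod(means[intersect(chains[[h]], names(means))])
      tail_target <- targets[[h]] * jit(1) / prefix
      tail_means <- pmin(0.9, tail_target^(1 / length(tail_ids)) *
                           jit(length(tail_ids), -0.1, 0.1))
      # re-anchor the last tail event so the product hits the target
      last <- tail_ids[length(tail_ids)]
      tail_means[length(tail_ids)] <-
        min(0.9, tail_target / prod(tail_means[-length(tail_ids)]))
      names(tail_means) <- tail_ids
      means <- c(means, tail_means)
    }
    means <- means[paste0("X", 1:14)]
    fams <- sample(c("uniform", "triangular", "beta", "log_uniform",
                     "point"), 14, replace = TRUE)
    dists <- purrr::map2(as.numeric(means), fams, random_dist_with_mean)
    list(means = means, dists = dists)
  })

  ids <- paste0("N", 1:14)
  ev_ids <- paste0("X", 1:14)
  overrides <- vector("list", 14)
  names(overrides) <- ev_ids
  overrides[["X1"]] <- list(dneg_females_cbp = dist_point(1))
  overrides[["X11"]] <- list(dneg_females_cbp = dist_point(1))

  inputs <- tibble::tibble(input_id = ids, dist = built$dists)
  events <- tibble::tibble(
    event_id = ev_ids,
    label = unname(labels[ev_ids]),
    input_ref = ids,
    overrides = unname(overrides)
  )
  harms <- tibble::tibble(
    harm_id = names(chains),
    label = c("HTR at index transfusion (synthetic)",
              "HTR at future transfusion (synthetic)",
              "HDFN death or disability (synthetic)"),
    chain = unname(chains)
  )
  populations <- tibble::tibble(
    population_id = c("all_recipients", "dneg_females_cbp"),
    label = c("All prehospital trauma recipients",
              "D-negative females of childbearing potential"),
    incidence_per_million_per_year = c(83, 83),
    population_size = c(67e6, 67e6),
    subgroup_fraction = c(1, 0.01798)
  )
  config <- model_config(inputs, events, harms, populations,
                         mc = list(seed = seed),
                         life_years = list(
                           survivor_life_years = dist_uniform(30, 50)
                         ))
  scenario_truth(config)
}
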