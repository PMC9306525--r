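# Analytic chain evaluation: harm probabilities from fixed per-event
# probabilities, additive harm combination, policy-mix scaling, and
# conditional fixing of one input.

# Effective distribution of an event for a population: the override if one
# exists, otherwise the referenced input's distribution.
event_dist <- function(config, event_id, population_id) {
  row <- which(config$events$event_id == event_id)
  if (!length(row)) {
    stop("unknown event `", event_id, "`", call. = FALSE)
  }
  ov <- config$events$overrides[[row]]
  if (!is.null(ov) && population_id %in% names(ov)) {
    return(ov[[population_id]])
  }
  ref <- config$events$input_ref[[row]]
  config$inputs$dist[[match(ref, config$inputs$input_id)]]
}

# Substream key for an event's draws: events sharing an input share its
# draws; a population override gets its own stream.
event_stream_key <- function(config, event_id, population_id) {
  row <- which(config$events$event_id == event_id)
  ov <- config$events$overrides[[row]]
  if (!is.null(ov) && population_id %in% names(ov)) {
    paste0("override:", event_id, "@", population_id)
  } else {
    paste0("input:", config$events$input_ref[[row]])
  }
}

harm_chain <- function(config, harm_id) {
  row <- which(config$harms$harm_id == harm_id)
  if (!length(row)) {
    stop("unknown harm `", harm_id, "`", call. = FALSE)
  }
  config$harms$chain[[row]]
}

#' Analytic harm probability along a chain
#'
#' Evaluates one harm's probability per transfusion as the product of the
#' conditional probabilities of the events along its chain. By default each
#' event contributes the mean of its input distribution (after population
#' overrides); `fixed_probabilities` replaces any subset of events with
#' explicit values, which is how scenario and what-if analyses condition
#' the chain.
#'
#' @param config A `dpr_config`.
#' @param harm_id Harm identifier.
#' @param fixed_probabilities Optional named numeric vector or list,
#'   `event_id -> probability in [0, 1]`.
#' @param population_id Population whose overrides apply (default: first
#'   population in the config).
#' @return A single probability in \[0, 1\].
#' @examples
#' cfg <- default_config()
#' chain_probability(cfg, "hdfn")
#' chain_probability(cfg, "hdfn", population_id = "dneg_females_cbp")
#' @export
chain_probability <- function(config, harm_id, fixed_probabilities = NULL,
                              population_id = config$populations$population_id[1]) {
  chain <- harm_chain(config, harm_id)
  fixed <- as.list(fixed_probabilities %||% list())
  probs <- vapply(chain, function(ev) {
    if (ev %in% names(fixed)) {
      p <- as.numeric(fixed[[ev]])
      if (is.na(p) || p < 0 || p > 1) {
        stop("fixed probability for event `", ev,
             "` must lie in [0, 1]", call. = FALSE)
      }
      p
    } else {
      dist_mean(event_dist(config, ev, population_id))
    }
  }, numeric(1))
  # sequential double-precision product, matching the simulator's
  # per-iteration accumulation bit for bit
  Reduce(`*`, probs, 1)
}

#' Combine per-harm probabilities into an any-harm probability
#'
#' The probability that any of several harms occurs is taken as the sum of
#' the individual harm probabilities, capped at 1. At the small
#' per-transfusion probabilities this model operates on, the additive form
#' and the exact union `1 - prod(1 - p)` agree to well below the display
#' precision; the exact form is available via `method = "union"`.
#'
#' @param harm_probabilities Numeric vector of probabilities in \[0, 1\].
#' @param method `"sum"` (default) or `"union"`.
#' @return A single probability.
#' @examples
#' combined_risk(c(1 / 570, 1 / 6600, 1 / 140000))
#' @export
combined_risk <- function(harm_probabilities, method = c("sum", "union")) {
  method <- match.arg(method)
  p <- as.numeric(harm_probabilities)
  if (!length(p)) stop("harm_probabilities must be non-empty", call. = FALSE)
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("harm probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (method == "sum") min(1, sum(p)) else 1 - prod(1 - p)
}

#' Scale a harm probability by the D-positive policy mix
#'
#' Under a mixed issuing policy only a fraction of prehospital transfusion
#' episodes use D-positive units; exposure, and hence each harm
#' probability, scales linearly with that fraction. `dpos_fraction = 1` is
#' the exclusive D-positive base case; `0.5` models a 50:50 mix with
#' D-negative units.
#'
#' @param harm_probability Probability (vectorised) in \[0, 1\].
#' @param dpos_fraction Fraction of episodes using D-positive units, in
#'   \[0, 1\].
#' @return Scaled probabilities.
#' @export
apply_policy_mix <- function(harm_probability, dpos_fraction) {
  if (length(dpos_fraction) != 1L || is.na(dpos_fraction) ||
      dpos_fraction < 0 || dpos_fraction > 1) {
    stop("dpos_fraction must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(harm_probability < 0 | harm_probability > 1, na.rm = TRUE)) {
    stop("harm_probability must lie in [0, 1]", call. = FALSE)
  }
  harm_probability * dpos_fraction
}

#' Fix one model input at an exact value
#'
#' Returns a configuration in which the named input's distribution is
#' replaced by a point mass at `fixed_value`, leaving every other input
#' untouched. Running the simulation on the result gives the risk
#' distribution conditional on that input being known exactly — the
#' "what if the alloimmunization rate were known to be 10%" style of
#' analysis, and the definition underlying the first-order sensitivity
#' index.
#'
#' @param config A `dpr_config`.
#' @param input_id Input to fix.
#' @param fixed_value Probability in \[0, 1\].
#' @return A modified `dpr_config`.
#' @export
conditional_fix <- function(config, input_id, fixed_value) {
  stopifnot(inherits(config, "dpr_config"))
  row <- match(input_id, config$inputs$input_id)
  if (is.na(row)) {
    stop("unknown input `", input_id, "`", call. = FALSE)
  }
  if (fixed_value < 0 || fixed_value > 1) {
    stop("fixed_value must lie in [0, 1]", call. = FALSE)
  }
  old <- config$inputs$dist[[row]]
  config$inputs$dist[[row]] <- dist_point(
    fixed_value,
    description = old$description,
    source_note = paste0("fixed at ", fixed_value, " by conditional_fix()")
  )
  config
}
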