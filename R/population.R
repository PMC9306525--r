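# Population and time scaling: annual transfusion counts and the expected
# number of years to first observation of each harm.

#' Annual prehospital transfusion count for a population
#'
#' Derives the expected number of prehospital transfusion episodes per year
#' from the incidence of major haemorrhage in trauma, the population size,
#' and (for subgroups) the fraction of the all-recipient count they
#' represent:
#' `incidence_per_million * population_size / 1e6 * subgroup_fraction`.
#'
#' @param incidence_per_million Major-haemorrhage incidence per million
#'   persons per year.
#' @param population_size Population size (persons).
#' @param subgroup_fraction Fraction of the all-recipient annual count in
#'   this subgroup (1 for all recipients).
#' @return Expected transfusion episodes per year.
#' @examples
#' annual_transfusions(83, 67e6) # all recipients in England
#' @export
annual_transfusions <- function(incidence_per_million, population_size,
                                subgroup_fraction = 1) {
  stopifnot(incidence_per_million >= 0, population_size >= 0,
            subgroup_fraction >= 0, subgroup_fraction <= 1)
  incidence_per_million * population_size / 1e6 * subgroup_fraction
}

#' Years until one harmful event is expected
#'
#' Converts a reciprocal risk ("one event per N transfusions") into the
#' expected number of years before one event is observed, given the annual
#' transfusion count: `risk_reciprocal / annual`. Applied to a credibility
#' interval endpoint it transforms the interval monotonically.
#'
#' @param risk_reciprocal Transfusions per event (vectorised).
#' @param annual Transfusion episodes per year (> 0).
#' @return Years to one expected event.
#' @examples
#' years_to_event(570, 100)
#' @export
years_to_event <- function(risk_reciprocal, annual) {
  if (length(annual) != 1L || is.na(annual) || annual <= 0) {
    stop("annual transfusion count must be a single positive number",
         call. = FALSE)
  }
  risk_reciprocal / annual
}

#' Annual projection of harms for a simulated population
#'
#' Combines a simulation result with the population definition in the
#' configuration to give, per harm, the annual transfusion count and the
#' expected years to one event (mean and credibility interval).
#'
#' @param risk A `dpr_risk` object.
#' @param config The `dpr_config` the simulation was run from.
#' @return A tibble with one row per harm: `population_id`, `harm_id`,
#'   `annual_transfusions`, `years_mean`, `years_lo`, `years_hi`.
#' @examples
#' cfg <- default_config()
#' annual_projection(run_simulation(cfg, "all_recipients"), cfg)
#' @export
annual_projection <- function(risk, config) {
  stopifnot(inherits(risk, "dpr_risk"), inherits(config, "dpr_config"))
  pop <- config$populations |>
    dplyr::filter(.data$population_id == risk$population_id)
  if (!nrow(pop)) {
    stop("population `", risk$population_id, "` not in config",
         call. = FALSE)
  }
  annual <- annual_transfusions(pop$incidence_per_million_per_year,
                                pop$population_size, pop$subgroup_fraction)
  risk$estimates |>
    dplyr::transmute(
      population_id = .data$population_id,
      harm_id = .data$harm_id,
      annual_transfusions = annual,
      years_mean = years_to_event(.data$reciprocal_mean, annual),
      years_lo = years_to_event(.data$reciprocal_lo, annual),
      years_hi = years_to_event(.data$reciprocal_hi, annual)
    )
}

#' Display tables of risks and years-to-event
#'
#' `risk_table()` renders a simulation result in the reporting style of the
#' field: reciprocal risks rounded to 2 significant figures with the
#' credibility interval alongside. `years_table()` does the same for an
#' [annual_projection()]. Raw (unrounded) values remain available from
#' `tidy()` / `annual_projection()`.
#'
#' @param risk A `dpr_risk` object.
#' @param projection A tibble from [annual_projection()].
#' @param digits Significant figures (default 2).
#' @return A tibble of display strings.
#' @export
risk_table <- function(risk, digits = 2) {
  stopifnot(inherits(risk, "dpr_risk"))
  fmt <- function(x) format(signif(x, digits), big.mark = ",",
                            scientific = FALSE, trim = TRUE)
  risk$estimates |>
    dplyr::transmute(
      harm_id = .data$harm_id,
      label = .data$label,
      one_event_every = fmt(.data$reciprocal_mean),
      ci = paste0("(", fmt(.data$reciprocal_lo), "-",
                  fmt(.data$reciprocal_hi), ")")
    )
}

#' @rdname risk_table
#' @export
years_table <- function(projection, digits = 2) {
  fmt <- function(x) format(signif(x, digits), big.mark = ",",
                            scientific = FALSE, trim = TRUE)
  projection |>
    dplyr::transmute(
      harm_id = .data$harm_id,
      annual_transfusions = round(.data$annual_transfusions),
      years_to_event = fmt(.data$years_mean),
      ci = paste0("(", fmt(.data$years_lo), "-", fmt(.data$years_hi), ")")
    )
}
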