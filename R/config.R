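# Model configuration: inputs, events, harms, populations, and the Monte
# Carlo / life-years settings, with validation of all cross-references.

CONFIG_SCHEMA_VERSION <- 1L

#' Assemble a model configuration
#'
#' A model configuration binds together the four tables that define the
#' risk model plus the simulation settings:
#'
#' * `inputs` — one row per model input: `input_id`, a `dist` list-column of
#'   [dist_spec] objects giving the probability distribution of that
#'   conditional probability.
#' * `events` — one row per chain event: `event_id`, `label`, `input_ref`
#'   (the input supplying its conditional probability) and an `overrides`
#'   list-column mapping population ids to replacement distributions (e.g.
#'   the probability that the recipient is D-negative is fixed at 1 for the
#'   D-negative female subgroup).
#' * `harms` — one row per harm: `harm_id`, `label` and a `chain`
#'   list-column of event ids, root first. The harm probability per
#'   transfusion is the product of the conditional event probabilities
#'   along its chain.
#' * `populations` — one row per recipient population: `population_id`,
#'   `label`, `incidence_per_million_per_year`, `population_size` and
#'   `subgroup_fraction` (the fraction of the all-recipient annual
#'   transfusion count falling in this subgroup).
#'
#' @param inputs,events,harms,populations Data frames as described above
#'   (coerced to tibbles).
#' @param mc List with `iterations` (default 1000), `seed` and `ci_level`
#'   (default 0.95).
#' @param life_years Optional list with `years_lost_per_hdfn_event`
#'   (default 83), `bootstrap_samples` (default 10000),
#'   `survivor_life_years` (a [dist_spec]; support in years, not restricted
#'   to \[0, 1\]) and `survival_benefit_grid` (ascending percentages).
#' @param validate Run [validate_config()]?
#' @return An object of class `dpr_config`.
#' @seealso [load_config()], [write_config()], [default_config()]
#' @export
model_config <- function(inputs, events, harms, populations,
                         mc = list(), life_years = NULL, validate = TRUE) {
  mc <- utils::modifyList(
    list(iterations = 1000L, seed = 1L, ci_level = 0.95), mc)
  if (!is.null(life_years)) {
    life_years <- utils::modifyList(
      list(years_lost_per_hdfn_event = 83,
           bootstrap_samples = 10000L,
           survivor_life_years = NULL,
           survival_benefit_grid = seq(0.1, 5, by = 0.1)),
      life_years)
  }
  cfg <- structure(
    list(
      schema_version = CONFIG_SCHEMA_VERSION,
      inputs = tibble::as_tibble(inputs),
      events = tibble::as_tibble(events),
      harms = tibble::as_tibble(harms),
      populations = tibble::as_tibble(populations),
      mc = mc,
      life_years = life_years
    ),
    class = "dpr_config"
  )
  if (validate) validate_config(cfg)
  cfg
}

#' @export
print.dpr_config <- function(x, ...) {
  cat("<dpr_config> schema v", x$schema_version, "\n", sep = "")
  cat("  inputs:      ", nrow(x$inputs), "\n", sep = "")
  cat("  events:      ", nrow(x$events), "\n", sep = "")
  cat("  harms:       ", nrow(x$harms),
      " (", paste(x$harms$harm_id, collapse = ", "), ")\n", sep = "")
  cat("  populations: ", nrow(x$populations),
      " (", paste(x$populations$population_id, collapse = ", "), ")\n",
      sep = "")
  cat("  mc: ", x$mc$iterations, " iterations, seed ", x$mc$seed,
      ", ci ", x$mc$ci_level, "\n", sep = "")
  invisible(x)
}

#' Validate a model configuration
#'
#' Checks every invariant: distribution parameters in range, all
#' `input_ref`s and chain event ids resolving, unique ids, non-empty chains
#' with no repeated events, population arithmetic well-defined, and Monte
#' Carlo settings sane. Errors name the offending id.
#'
#' @param config A `dpr_config` object.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "dpr_config"))
  ins <- config$inputs
  if (anyDuplicated(ins$input_id)) {
    stop("duplicate input_id: ",
         paste(unique(ins$input_id[duplicated(ins$input_id)]), collapse = ", "),
         call. = FALSE)
  }
  purrr::walk2(ins$dist, ins$input_id, function(d, id) {
    validate_dist(d, unit_interval = TRUE, id = id)
  })

  ev <- config$events
  if (anyDuplicated(ev$event_id)) {
    stop("duplicate event_id: ",
         paste(unique(ev$event_id[duplicated(ev$event_id)]), collapse = ", "),
         call. = FALSE)
  }
  missing_ref <- setdiff(ev$input_ref, ins$input_id)
  if (length(missing_ref)) {
    stop("event input_ref does not resolve to any input: `",
         paste(missing_ref, collapse = "`, `"), "`", call. = FALSE)
  }
  pop_ids <- config$populations$population_id
  purrr::walk2(ev$overrides, ev$event_id, function(ov, id) {
    if (is.null(ov)) return(invisible())
    bad_pop <- setdiff(names(ov), pop_ids)
    if (length(bad_pop)) {
      stop("event `", id, "`: override names unknown population `",
           paste(bad_pop, collapse = "`, `"), "`", call. = FALSE)
    }
    purrr::iwalk(ov, function(d, pop) {
      validate_dist(d, unit_interval = TRUE,
                    id = paste0(id, " override for ", pop))
    })
  })

  hm <- config$harms
  if (anyDuplicated(hm$harm_id)) {
    stop("duplicate harm_id: ",
         paste(unique(hm$harm_id[duplicated(hm$harm_id)]), collapse = ", "),
         call. = FALSE)
  }
  purrr::walk2(hm$chain, hm$harm_id, function(chain, id) {
    if (length(chain) == 0) {
      stop("harm `", id, "`: chain is empty", call. = FALSE)
    }
    if (anyDuplicated(chain)) {
      stop("harm `", id, "`: repeated event in chain: ",
           paste(unique(chain[duplicated(chain)]), collapse = ", "),
           call. = FALSE)
    }
    dangling <- setdiff(chain, ev$event_id)
    if (length(dangling)) {
      stop("harm `", id, "`: chain references unknown event `",
           paste(dangling, collapse = "`, `"), "`", call. = FALSE)
    }
  })

  pp <- config$populations
  if (anyDuplicated(pp$population_id)) {
    stop("duplicate population_id: ",
         paste(unique(pp$population_id[duplicated(pp$population_id)]),
               collapse = ", "), call. = FALSE)
  }
  purrr::pwalk(pp, function(population_id, incidence_per_million_per_year,
                            population_size, subgroup_fraction, ...) {
    if (incidence_per_million_per_year < 0) {
      stop("population `", population_id,
           "`: incidence_per_million_per_year must be non-negative",
           call. = FALSE)
    }
    if (population_size <= 0) {
      stop("population `", population_id,
           "`: population_size must be positive", call. = FALSE)
    }
    if (subgroup_fraction < 0 || subgroup_fraction > 1) {
      stop("population `", population_id,
           "`: subgroup_fraction must lie in [0, 1]", call. = FALSE)
    }
  })

  mc <- config$mc
  if (mc$iterations < 1) stop("mc$iterations must be >= 1", call. = FALSE)
  if (mc$ci_level < 0 || mc$ci_level >= 1) {
    stop("mc$ci_level must lie in [0, 1)", call. = FALSE)
  }

  ly <- config$life_years
  if (!is.null(ly)) {
    if (ly$years_lost_per_hdfn_event <= 0) {
      stop("life_years$years_lost_per_hdfn_event must be positive",
           call. = FALSE)
    }
    if (ly$bootstrap_samples < 1) {
      stop("life_years$bootstrap_samples must be >= 1", call. = FALSE)
    }
    if (!is.null(ly$survivor_life_years)) {
      validate_dist(ly$survivor_life_years, unit_interval = FALSE,
                    id = "survivor_life_years")
    }
    grid <- ly$survival_benefit_grid
    if (is.unsorted(grid, strictly = FALSE)) {
      stop("life_years$survival_benefit_grid must be sorted ascending",
           call. = FALSE)
    }
  }
  invisible(config)
}

# ---- (de)serialization --------------------------------------------------

dist_to_list <- function(d) {
  out <- list(family = d$family, params = d$params)
  if (!is.null(d$description)) out$description <- d$description
  if (!is.null(d$source_note)) out$source_note <- d$source_note
  out
}

dist_from_list <- function(x, where = "distribution") {
  if (is.null(x$family) || is.null(x$params)) {
    stop("malformed distribution for ", where,
         ": needs `family` and `params`", call. = FALSE)
  }
  new_dist(x$family, lapply(x$params, as.numeric),
           description = x$description, source_note = x$source_note)
}

config_to_list <- function(config) {
  list(
    schema_version = config$schema_version,
    inputs = purrr::map2(config$inputs$input_id, config$inputs$dist,
                         function(id, d) c(list(id = id), dist_to_list(d))),
    events = purrr::pmap(config$events, function(event_id, label, input_ref,
                                                 overrides, ...) {
      out <- list(id = event_id, label = label, input = input_ref)
      if (!is.null(overrides) && length(overrides)) {
        out$population_overrides <- lapply(overrides, dist_to_list)
      }
      out
    }),
    harms = purrr::pmap(config$harms, function(harm_id, label, chain, ...) {
      list(id = harm_id, label = label, chain = as.list(chain))
    }),
    populations = purrr::pmap(config$populations, function(population_id,
        label, incidence_per_million_per_year, population_size,
        subgroup_fraction, ...) {
      list(id = population_id, label = label,
           incidence_per_million_per_year = incidence_per_million_per_year,
           population_size = population_size,
           subgroup_fraction = subgroup_fraction)
    }),
    mc = config$mc,
    life_years = if (!is.null(config$life_years)) {
      ly <- config$life_years
      out <- list(
        years_lost_per_hdfn_event = ly$years_lost_per_hdfn_event,
        bootstrap_samples = ly$bootstrap_samples,
        survival_benefit_grid = as.list(ly$survival_benefit_grid)
      )
      if (!is.null(ly$survivor_life_years)) {
        out$survivor_life_years <- dist_to_list(ly$survivor_life_years)
      }
      out
    }
  )
}

config_from_list <- function(x, context = "config") {
  if (is.null(x$inputs) || is.null(x$events) || is.null(x$harms) ||
      is.null(x$populations)) {
    stop(context, ": requires `inputs`, `events`, `harms` and `populations` ",
         "sections", call. = FALSE)
  }
  inputs <- tibble::tibble(
    input_id = purrr::map_chr(x$inputs, function(i) {
      if (is.null(i$id)) stop(context, ": input without an `id`",
                              call. = FALSE)
      i$id
    }),
    dist = purrr::map(x$inputs, function(i) {
      dist_from_list(i, where = paste0("input `", i$id, "`"))
    })
  )
  events <- tibble::tibble(
    event_id = purrr::map_chr(x$events, "id"),
    label = purrr::map_chr(x$events, function(e) e$label %||% e$id),
    input_ref = purrr::map_chr(x$events, "input"),
    overrides = purrr::map(x$events, function(e) {
      ov <- e$population_overrides
      if (is.null(ov)) return(NULL)
      purrr::imap(ov, function(d, pop) {
        dist_from_list(d, where = paste0("event `", e$id,
                                         "` override for `", pop, "`"))
      })
    })
  )
  harms <- tibble::tibble(
    harm_id = purrr::map_chr(x$harms, "id"),
    label = purrr::map_chr(x$harms, function(h) h$label %||% h$id),
    chain = purrr::map(x$harms, function(h) as.character(unlist(h$chain)))
  )
  populations <- tibble::tibble(
    population_id = purrr::map_chr(x$populations, "id"),
    label = purrr::map_chr(x$populations, function(p) p$label %||% p$id),
    incidence_per_million_per_year =
      purrr::map_dbl(x$populations, "incidence_per_million_per_year"),
    population_size = purrr::map_dbl(x$populations, "population_size"),
    subgroup_fraction =
      purrr::map_dbl(x$populations,
                     function(p) p$subgroup_fraction %||% 1)
  )
  ly <- x$life_years
  if (!is.null(ly) && !is.null(ly$survivor_life_years)) {
    ly$survivor_life_years <- dist_from_list(ly$survivor_life_years,
                                             where = "survivor_life_years")
  }
  if (!is.null(ly) && !is.null(ly$survival_benefit_grid)) {
    ly$survival_benefit_grid <- as.numeric(unlist(ly$survival_benefit_grid))
  }
  mc <- x$mc %||% list()
  model_config(inputs, events, harms, populations, mc = mc, life_years = ly)
}

#' Read and write model configurations
#'
#' Configurations are stored as YAML documents with `inputs`, `events`,
#' `harms`, `populations`, `mc` and `life_years` sections (see the shipped
#' example returned by [default_config_path()]). `load_config()` parses and
#' fully validates; `write_config()` round-trips:
#' `load_config(write_config(cfg))` reproduces `cfg`.
#'
#' @param path Path to a YAML configuration file.
#' @param config A `dpr_config` object.
#' @return `load_config()` returns a validated `dpr_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  x <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("failed to parse config `", path, "`: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  config_from_list(x, context = path)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "dpr_config"))
  # emit doubles at 17 significant digits so every parameter round-trips
  # bit-exactly (the default emitter truncates)
  yaml::write_yaml(
    config_to_list(config), path,
    handlers = list(numeric = function(v) {
      structure(sprintf("%.17g", v), class = "verbatim")
    })
  )
  invisible(path)
}

#' Export a validated configuration as JSON
#'
#' @param config A `dpr_config` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "dpr_config"))
  js <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' The shipped default configuration
#'
#' `default_config_path()` returns the path of the example configuration
#' installed with the package; `default_config()` loads it. The
#' configuration has the full 14-event chain structure, the three harms
#' (index haemolytic transfusion reaction, future HTR, and HDFN death or
#' disability), and the two recipient populations (all prehospital trauma
#' recipients in England, and the D-negative females of childbearing
#' potential subgroup). Its input distributions are uniform placeholder
#' bands around plausible values and are clearly marked as such in each
#' `source_note`: reproducing published risk estimates requires
#' transcribing the original study's input distributions over these
#' placeholders.
#'
#' @return A file path, or a validated `dpr_config`.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "dposrisk",
              mustWork = TRUE)
}

#' @rdname default_config_path
#' @export
default_config <- function() {
  load_config(default_config_path())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
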