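# Monte Carlo propagation of input uncertainty through the event chain,
# with equal-tailed credibility intervals and reciprocal "1 in N" reporting.

#' Run the Monte Carlo risk simulation
#'
#' For each iteration one value is drawn from every model input's
#' distribution; each harm's probability for that iteration is the product
#' of the drawn conditional probabilities along its chain, and the
#' "any harm" probability is their sum (capped at 1). Draws use one
#' deterministic substream per input derived from the root seed, so results
#' are bit-reproducible for a given seed and adding or re-typing one input
#' never perturbs the draws of the others. Events that share an input share
#' its draws within an iteration; population overrides draw from their own
#' substream.
#'
#' @param config A `dpr_config`.
#' @param population_id Population whose overrides apply.
#' @param iterations,seed,ci_level Override the config's `mc` settings.
#' @return An object of class `dpr_risk`: a list with
#'   * `estimates` — tibble with one row per harm plus the combined
#'     `any_harm` row: mean probability, equal-tailed credibility interval,
#'     and the reciprocal forms (`reciprocal_mean` = 1 / mean probability;
#'     `reciprocal_lo`/`reciprocal_hi` = reciprocals of the CI endpoints,
#'     sorted ascending);
#'   * `samples` — iterations x harms matrix of per-iteration harm
#'     probabilities;
#'   * `population_id`, `iterations`, `seed`, `ci_level`.
#' @examples
#' risk <- run_simulation(default_config(), "all_recipients")
#' tidy(risk)
#' @export
run_simulation <- function(config, population_id,
                           iterations = NULL, seed = NULL, ci_level = NULL) {
  stopifnot(inherits(config, "dpr_config"))
  if (!population_id %in% config$populations$population_id) {
    stop("unknown population `", population_id, "`", call. = FALSE)
  }
  iterations <- as.integer(iterations %||% config$mc$iterations)
  seed <- seed %||% config$mc$seed
  ci_level <- ci_level %||% config$mc$ci_level

  draws <- draw_event_matrix(config, population_id, iterations, seed)

  harm_ids <- config$harms$harm_id
  samples <- matrix(NA_real_, nrow = iterations,
                    ncol = length(harm_ids) + 1L,
                    dimnames = list(NULL, c(harm_ids, "any_harm")))
  for (h in harm_ids) {
    chain <- harm_chain(config, h)
    prob <- rep(1, iterations)
    for (ev in chain) prob <- prob * draws[[ev]]
    samples[, h] <- prob
  }
  samples[, "any_harm"] <- pmin(1, rowSums(samples[, harm_ids, drop = FALSE]))

  labels <- c(config$harms$label, "Any of the modelled harms")
  estimates <- purrr::map2_dfr(
    colnames(samples), labels,
    function(h, lab) summarize_samples(samples[, h], h, lab, ci_level)
  )
  estimates$population_id <- population_id

  structure(
    list(
      estimates = estimates,
      samples = samples,
      population_id = population_id,
      iterations = iterations,
      seed = seed,
      ci_level = ci_level
    ),
    class = "dpr_risk"
  )
}

# One column of draws per event in any harm chain (shared inputs share
# columns by drawing once per substream key).
draw_event_matrix <- function(config, population_id, iterations, seed) {
  events <- unique(unlist(config$harms$chain))
  keys <- vapply(events, function(ev) {
    event_stream_key(config, ev, population_id)
  }, character(1))
  by_key <- new.env(parent = emptyenv())
  draws <- list()
  for (i in seq_along(events)) {
    key <- keys[[i]]
    if (!exists(key, envir = by_key, inherits = FALSE)) {
      spec <- event_dist(config, events[[i]], population_id)
      assign(key, draw_stream(spec, iterations, seed, key), envir = by_key)
    }
    draws[[events[[i]]]] <- get(key, envir = by_key, inherits = FALSE)
  }
  draws
}

summarize_samples <- function(x, harm_id, label, ci_level) {
  ci <- credibility_interval(x, ci_level)
  m <- mean(x)
  rec_ci <- sort(c(to_reciprocal(ci[[2]]), to_reciprocal(ci[[1]])))
  tibble::tibble(
    harm_id = harm_id,
    label = label,
    mean_probability = m,
    ci_low_probability = ci[[1]],
    ci_high_probability = ci[[2]],
    reciprocal_mean = to_reciprocal(m),
    reciprocal_lo = rec_ci[[1]],
    reciprocal_hi = rec_ci[[2]]
  )
}

#' Equal-tailed credibility interval of Monte Carlo samples
#'
#' Empirical quantiles at `(1 - level) / 2` and `1 - (1 - level) / 2`,
#' using linear interpolation between order statistics
#' (`stats::quantile()` type 7). `level = 0` degenerates to the median
#' twice.
#'
#' @param samples Non-empty numeric vector.
#' @param level Credibility level in \[0, 1).
#' @return Numeric vector `c(lower, upper)`, sorted ascending.
#' @examples
#' credibility_interval(1:1000, 0.95)
#' @export
credibility_interval <- function(samples, level = 0.95) {
  if (!length(samples)) stop("samples must be non-empty", call. = FALSE)
  if (is.na(level) || level < 0 || level >= 1) {
    stop("level must lie in [0, 1)", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  unname(stats::quantile(samples, probs = c(alpha, 1 - alpha),
                         type = 7, names = FALSE))
}

#' Reciprocal risk form
#'
#' Risks are communicated as "one event per N transfusions" with
#' N = 1 / probability. `to_reciprocal()` returns the raw reciprocal
#' (`Inf` for a zero probability: no events expected);
#' `format_reciprocal()` renders the display form rounded to 2 significant
#' figures, matching the reporting convention of the risk tables.
#'
#' @param p Probability (vectorised), each value > 0 (0 maps to `Inf`).
#' @param digits Significant figures for display (default 2).
#' @return `to_reciprocal()`: numeric; `format_reciprocal()`: character,
#'   e.g. `"1 in 500"`, with `"no events expected"` for zero probability.
#' @examples
#' to_reciprocal(0.002)
#' format_reciprocal(0.002)
#' @export
to_reciprocal <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p == 0, Inf, 1 / p)
}

#' @rdname to_reciprocal
#' @export
format_reciprocal <- function(p, digits = 2) {
  rec <- to_reciprocal(p)
  ifelse(is.infinite(rec), "no events expected",
         paste0("1 in ", format(signif(rec, digits),
                                big.mark = ",", scientific = FALSE,
                                trim = TRUE)))
}

#' @export
print.dpr_risk <- function(x, ...) {
  cat("<dpr_risk> population `", x$population_id, "`, ",
      x$iterations, " iterations, seed ", x$seed, ", ",
      format(100 * x$ci_level), "% credibility intervals\n\n", sep = "")
  tab <- x$estimates
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s %s  (CI %s - %s)\n",
                tab$harm_id[i],
                format_reciprocal(tab$mean_probability[i]),
                format(signif(tab$reciprocal_lo[i], 2), big.mark = ","),
                format(signif(tab$reciprocal_hi[i], 2), big.mark = ",")))
  }
  invisible(x)
}

#' Tidy and summarize simulation results
#'
#' `tidy()` returns the per-harm estimates tibble (one row per harm plus
#' the combined `any_harm` row); `glance()` returns a one-row run summary.
#'
#' @param x A `dpr_risk` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dpr_risk
#' @export
tidy.dpr_risk <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.dpr_risk
#' @method glance dpr_risk
#' @export
glance.dpr_risk <- function(x, ...) {
  tibble::tibble(
    population_id = x$population_id,
    iterations = x$iterations,
    seed = x$seed,
    ci_level = x$ci_level,
    n_harms = ncol(x$samples) - 1L
  )
}

#' Plot the Monte Carlo harm-probability distributions
#'
#' Histogram of the per-iteration harm probabilities on a log10 axis,
#' faceted by harm, with the mean and credibility-interval bounds marked.
#'
#' @param object A `dpr_risk` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dpr_risk
#' @export
autoplot.dpr_risk <- function(object, bins = 40, ...) {
  df <- tibble::as_tibble(object$samples) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "harm_id", values_to = "probability") |>
    dplyr::filter(.data$probability > 0)
  marks <- object$estimates |>
    tidyr::pivot_longer(
      c("mean_probability", "ci_low_probability", "ci_high_probability"),
      names_to = "stat", values_to = "probability"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$probability,
                   linetype = .data$stat),
      colour = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~harm_id, scales = "free") +
    ggplot2::labs(
      x = "harm probability per transfusion (log scale)",
      y = "iterations",
      title = paste0("Simulated harm probabilities - ",
                     object$population_id)
    ) +
    ggplot2::theme_minimal()
}

#' Write simulation results to disk
#'
#' Writes the estimates as CSV (raw values) and JSON (raw plus
#' display-rounded forms), and optionally the per-iteration samples.
#'
#' @param risk A `dpr_risk` object.
#' @param dir Output directory (created if needed).
#' @param samples Also write the per-iteration sample matrix as CSV?
#' @return Invisibly, a character vector of the files written.
#' @export
write_risk <- function(risk, dir, samples = FALSE) {
  stopifnot(inherits(risk, "dpr_risk"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  csv <- file.path(dir, paste0("risk_", risk$population_id, ".csv"))
  utils::write.csv(risk$estimates, csv, row.names = FALSE)
  files <- c(files, csv)

  disp <- risk$estimates
  disp$display <- format_reciprocal(disp$mean_probability)
  js <- file.path(dir, paste0("risk_", risk$population_id, ".json"))
  jsonlite::write_json(
    list(
      population_id = risk$population_id,
      iterations = risk$iterations,
      seed = risk$seed,
      ci_level = risk$ci_level,
      estimates = disp
    ),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- c(files, js)

  if (samples) {
    sm <- file.path(dir, paste0("samples_", risk$population_id, ".csv"))
    utils::write.csv(
      cbind(iteration = seq_len(nrow(risk$samples)), risk$samples),
      sm, row.names = FALSE
    )
    files <- c(files, sm)
  }
  invisible(files)
}
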