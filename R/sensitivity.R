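# Variance-based sensitivity analysis: first-order Sobol indices by the
# pick-freeze (Saltelli) estimator, plus scatterplot export.
#
# The first-order index S_i = Var(E[Y | N_i]) / Var(Y) is the expected
# proportional reduction in the variance of the final risk estimate if
# input N_i could be fixed at an exact value.

#' First-order Sobol indices by pick-freeze estimation
#'
#' Estimates `S_i = Var(E[Y | X_i]) / Var(Y)` for each input of an
#' arbitrary model using the pick-freeze scheme: two independent sample
#' matrices A and B are drawn; for each input `i` the model is re-evaluated
#' on `AB_i` (matrix A with column `i` taken from B), and
#' `S_i = mean(f(B) * (f(AB_i) - f(A))) / Var(Y)`.
#'
#' @param model Function taking an `n x k` matrix with named columns and
#'   returning a numeric vector of length `n`.
#' @param samplers Named list, one entry per input: either a [dist_spec]
#'   or a function `n -> draws`.
#' @param n Rows per sample matrix (total model evaluations are
#'   `n * (k + 2)`).
#' @param seed Root seed; every input draws from its own substream.
#' @return A tibble with `input_id`, `s_index` (raw estimate) and
#'   `s_index_clipped` (negative estimator noise clipped to 0), plus the
#'   output variance and `n` as attributes. If `Var(Y) = 0` all indices
#'   are defined as 0 with a warning.
#' @examples
#' # Y = X1 + 2 * X2 with uniform(0,1) inputs: S1 = 0.2, S2 = 0.8
#' sobol_first_order(
#'   function(X) X[, "x1"] + 2 * X[, "x2"],
#'   list(x1 = dist_uniform(0, 1), x2 = dist_uniform(0, 1)),
#'   n = 4096, seed = 1
#' )
#' @export
sobol_first_order <- function(model, samplers, n = 2^14, seed = 1L) {
  k <- length(samplers)
  ids <- names(samplers)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("samplers must be a named list", call. = FALSE)
  }
  draw <- function(tag) {
    cols <- lapply(ids, function(id) {
      s <- samplers[[id]]
      key <- paste0("sobol", tag, ":", id)
      if (inherits(s, "dpr_dist")) {
        draw_stream(s, n, seed, key)
      } else {
        with_stream(substream_seed(seed, key), function() s(n))
      }
    })
    m <- do.call(cbind, cols)
    colnames(m) <- ids
    m
  }
  A <- draw("A")
  B <- draw("B")
  fA <- model(A)
  fB <- model(B)
  var_y <- stats::var(c(fA, fB))
  s <- vapply(ids, function(id) {
    if (var_y == 0) return(0)
    ABi <- A
    ABi[, id] <- B[, id]
    mean(fB * (model(ABi) - fA)) / var_y
  }, numeric(1))
  if (var_y == 0) {
    warning("output variance is zero; all sensitivity indices defined as 0")
  }
  out <- tibble::tibble(
    input_id = ids,
    s_index = unname(s),
    s_index_clipped = pmax(0, unname(s))
  )
  attr(out, "var_y") <- var_y
  attr(out, "n") <- n
  out
}

# Model closure for a configured harm (or the combined any-harm output) as
# a function of the per-stream input draws.
config_model <- function(config, population_id, harm_id) {
  events <- unique(unlist(config$harms$chain))
  keys <- vapply(events, function(ev) {
    event_stream_key(config, ev, population_id)
  }, character(1))
  names(keys) <- events
  harm_ids <- config$harms$harm_id
  function(X) {
    per_harm <- sapply(harm_ids, function(h) {
      chain <- harm_chain(config, h)
      prob <- rep(1, nrow(X))
      for (ev in chain) prob <- prob * X[, keys[[ev]]]
      prob
    })
    if (harm_id == "any_harm") {
      pmin(1, rowSums(as.matrix(per_harm)))
    } else {
      as.matrix(per_harm)[, harm_id]
    }
  }
}

config_samplers <- function(config, population_id) {
  events <- unique(unlist(config$harms$chain))
  samplers <- list()
  for (ev in events) {
    key <- event_stream_key(config, ev, population_id)
    if (is.null(samplers[[key]])) {
      samplers[[key]] <- event_dist(config, ev, population_id)
    }
  }
  samplers
}

#' Sensitivity indices for a configured risk model
#'
#' Computes the first-order Sobol index of every model input with respect
#' to one harm output (or the combined any-harm output) for a given
#' population. Inputs fixed by a population override contribute through
#' their override distribution (a point-mass override has index 0 by
#' construction).
#'
#' @param config A `dpr_config`.
#' @param population_id Population whose overrides apply.
#' @param harm_id A harm id or `"any_harm"` (default).
#' @param n Rows per pick-freeze sample matrix.
#' @param seed Root seed.
#' @return An object of class `dpr_sensitivity`: the index tibble (rows
#'   named by `input_id`, override streams as `event@population`) plus
#'   estimator metadata.
#' @examples
#' sens <- sensitivity_indices(default_config(), "dneg_females_cbp",
#'                             n = 2048)
#' tidy(sens)
#' @export
sensitivity_indices <- function(config, population_id,
                                harm_id = "any_harm", n = 2^13, seed = 1L) {
  stopifnot(inherits(config, "dpr_config"))
  if (harm_id != "any_harm" && !harm_id %in% config$harms$harm_id) {
    stop("unknown harm `", harm_id, "`", call. = FALSE)
  }
  samplers <- config_samplers(config, population_id)
  model <- config_model(config, population_id, harm_id)
  idx <- sobol_first_order(model, samplers, n = n, seed = seed)
  idx$input_id <- sub("^input:", "", idx$input_id)
  idx$input_id <- sub("^override:", "", idx$input_id)
  structure(
    list(
      indices = idx,
      harm_id = harm_id,
      population_id = population_id,
      n = n,
      seed = seed,
      var_y = attr(idx, "var_y")
    ),
    class = "dpr_sensitivity"
  )
}

#' @export
print.dpr_sensitivity <- function(x, ...) {
  cat("<dpr_sensitivity> output `", x$harm_id, "`, population `",
      x$population_id, "`, n = ", x$n, " per matrix\n", sep = "")
  ord <- order(-x$indices$s_index_clipped)
  for (i in ord) {
    cat(sprintf("  %-24s S = %6.3f\n", x$indices$input_id[i],
                x$indices$s_index_clipped[i]))
  }
  invisible(x)
}

#' Tidy and summarize sensitivity results
#'
#' @param x A `dpr_sensitivity` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dpr_sensitivity
#' @export
tidy.dpr_sensitivity <- function(x, ...) {
  x$indices
}

#' @rdname tidy.dpr_sensitivity
#' @method glance dpr_sensitivity
#' @export
glance.dpr_sensitivity <- function(x, ...) {
  tibble::tibble(
    harm_id = x$harm_id,
    population_id = x$population_id,
    n = x$n,
    seed = x$seed,
    var_y = x$var_y,
    sum_s = sum(x$indices$s_index)
  )
}

#' Plot first-order sensitivity indices
#'
#' @param object A `dpr_sensitivity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dpr_sensitivity
#' @export
autoplot.dpr_sensitivity <- function(object, ...) {
  df <- object$indices
  df$input_id <- stats::reorder(df$input_id, df$s_index_clipped)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_index_clipped,
                                   y = .data$input_id)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = expression(S[i]),
      y = NULL,
      title = paste0("First-order sensitivity of `", object$harm_id, "` (",
                     object$population_id, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Scatterplot pairs of one input against the simulated output
#'
#' Exports per-iteration (input draw, output draw) pairs using exactly the
#' same substream draws as [run_simulation()] under the same seed, so the
#' scatter describes the simulation actually run.
#'
#' @param config A `dpr_config`.
#' @param population_id Population whose overrides apply.
#' @param input_id The input to place on the x-axis.
#' @param harm_id A harm id or `"any_harm"` (default).
#' @param iterations,seed Override the config's `mc` settings.
#' @return A tibble with `iteration`, `input_value`, `output_value`.
#' @examples
#' scatter_pairs(default_config(), "dneg_females_cbp", "N6",
#'               iterations = 200)
#' @export
scatter_pairs <- function(config, population_id, input_id,
                          harm_id = "any_harm",
                          iterations = NULL, seed = NULL) {
  stopifnot(inherits(config, "dpr_config"))
  row <- match(input_id, config$inputs$input_id)
  if (is.na(row)) stop("unknown input `", input_id, "`", call. = FALSE)
  iterations <- as.integer(iterations %||% config$mc$iterations)
  seed <- seed %||% config$mc$seed

  draws <- draw_event_matrix(config, population_id, iterations, seed)
  harm_ids <- config$harms$harm_id
  per_harm <- sapply(harm_ids, function(h) {
    chain <- harm_chain(config, h)
    prob <- rep(1, iterations)
    for (ev in chain) prob <- prob * draws[[ev]]
    prob
  })
  output <- if (harm_id == "any_harm") {
    pmin(1, rowSums(as.matrix(per_harm)))
  } else {
    if (!harm_id %in% harm_ids) {
      stop("unknown harm `", harm_id, "`", call. = FALSE)
    }
    as.matrix(per_harm)[, harm_id]
  }
  input_value <- draw_stream(config$inputs$dist[[row]], iterations, seed,
                             paste0("input:", input_id))
  tibble::tibble(
    iteration = seq_len(iterations),
    input_value = input_value,
    output_value = output
  )
}

#' Plot an input-output scatter
#'
#' @param pairs A tibble from [scatter_pairs()].
#' @param log_y Use a log10 output axis?
#' @return A ggplot object.
#' @export
plot_scatter <- function(pairs, log_y = TRUE) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$input_value,
                                           y = .data$output_value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "input value", y = "harm probability") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
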