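# Life-years trade-off: survival benefit of prehospital whole blood versus
# life-years lost to HDFN in future pregnancies, via bootstrap.

#' Expected life-years lost to HDFN per transfusion
#'
#' Each HDFN death or lifelong disability is equated to a fixed number of
#' life-years lost (default 83, life expectancy at birth), so the expected
#' loss per transfusion is the per-transfusion HDFN probability times that
#' constant.
#'
#' @param hdfn_probability Per-transfusion HDFN harm probability
#'   (vectorised).
#' @param years_per_event Life-years lost per HDFN event (default 83).
#' @return Expected life-years lost per transfusion.
#' @examples
#' expected_life_years_lost(1 / 570)
#' @export
expected_life_years_lost <- function(hdfn_probability, years_per_event = 83) {
  stopifnot(all(hdfn_probability >= 0), years_per_event >= 0)
  hdfn_probability * years_per_event
}

#' Break-even survival benefit via bootstrap
#'
#' For each bootstrap replicate, one HDFN harm probability is resampled
#' from the Monte Carlo simulation output and one survivor life-years value
#' is drawn from its distribution. A candidate survival benefit of `s`
#' percent then gains `s / 100 * survivor life-years` per transfused
#' patient and loses `HDFN probability * years_per_event`. For every grid
#' value the function reports the fraction of replicates in which the gain
#' is at least the loss, and the break-even benefit is the smallest grid
#' value at which that fraction reaches `conf` (default 0.95).
#'
#' Gains and losses are compared per transfused patient in the subgroup, so
#' population scaling cancels. The comparison is `gained >= lost`, making a
#' zero HDFN risk break even at 0% benefit.
#'
#' @param hdfn_samples Per-iteration HDFN harm probabilities, e.g.
#'   `run_simulation(cfg, "dneg_females_cbp")$samples[, "hdfn"]`.
#' @param survivor_life_years A [dist_spec] for life-years gained per life
#'   saved (support in years; not restricted to \[0, 1\]).
#' @param years_per_event Life-years lost per HDFN event (default 83).
#' @param benefit_grid Ascending grid of survival improvements, in percent.
#' @param bootstrap_samples Number of bootstrap replicates (default 10000).
#' @param seed Root seed for the bootstrap resampling and survivor draws.
#' @param conf Confidence level defining break-even (default 0.95).
#' @return An object of class `dpr_tradeoff` with a `grid` tibble
#'   (`benefit_pct`, `prob_gain_exceeds_loss`), `break_even_benefit`
#'   (`NA` when not reached within the grid), and `reached`.
#' @examples
#' tr <- tradeoff_bootstrap(rep(1 / 570, 100), dist_point(40),
#'                          benefit_grid = seq(0, 2, by = 0.01))
#' tr$break_even_benefit
#' @export
tradeoff_bootstrap <- function(hdfn_samples, survivor_life_years,
                               years_per_event = 83,
                               benefit_grid = seq(0.1, 5, by = 0.1),
                               bootstrap_samples = 10000L,
                               seed = 1L, conf = 0.95) {
  if (!length(hdfn_samples)) {
    stop("hdfn_samples must be non-empty", call. = FALSE)
  }
  validate_dist(survivor_life_years, unit_interval = FALSE,
                id = "survivor_life_years")
  if (is.unsorted(benefit_grid)) {
    stop("benefit_grid must be sorted ascending", call. = FALSE)
  }
  B <- as.integer(bootstrap_samples)

  hdfn_boot <- with_stream(substream_seed(seed, "bootstrap:hdfn"), function() {
    hdfn_samples[sample.int(length(hdfn_samples), B, replace = TRUE)]
  })
  survivor <- draw_stream(survivor_life_years, B, seed, "bootstrap:survivor")

  lost <- expected_life_years_lost(hdfn_boot, years_per_event)
  # smallest benefit (percent) at which this replicate's gain >= loss
  s_star <- ifelse(survivor > 0, 100 * lost / survivor,
                   ifelse(lost == 0, 0, Inf))
  prob <- vapply(benefit_grid, function(s) mean(s_star <= s), numeric(1))

  idx <- which(prob >= conf)
  reached <- length(idx) > 0
  structure(
    list(
      grid = tibble::tibble(benefit_pct = benefit_grid,
                            prob_gain_exceeds_loss = prob),
      break_even_benefit = if (reached) benefit_grid[min(idx)] else NA_real_,
      reached = reached,
      conf = conf,
      years_per_event = years_per_event,
      bootstrap_samples = B,
      seed = seed
    ),
    class = "dpr_tradeoff"
  )
}

#' @export
print.dpr_tradeoff <- function(x, ...) {
  cat("<dpr_tradeoff> ", x$bootstrap_samples, " bootstrap replicates, ",
      x$years_per_event, " life-years lost per HDFN event\n", sep = "")
  if (x$reached) {
    cat(sprintf(
      "  break-even survival benefit at %.0f%% confidence: %.2f%%\n",
      100 * x$conf, x$break_even_benefit))
  } else {
    cat("  break-even not reached within the benefit grid\n")
  }
  invisible(x)
}

#' Tidy and summarize a life-years trade-off
#'
#' `tidy()` returns the per-grid-point probabilities; `glance()` a one-row
#' summary with the break-even benefit.
#'
#' @param x A `dpr_tradeoff` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dpr_tradeoff
#' @export
tidy.dpr_tradeoff <- function(x, ...) {
  x$grid
}

#' @rdname tidy.dpr_tradeoff
#' @method glance dpr_tradeoff
#' @export
glance.dpr_tradeoff <- function(x, ...) {
  tibble::tibble(
    break_even_benefit = x$break_even_benefit,
    reached = x$reached,
    conf = x$conf,
    years_per_event = x$years_per_event,
    bootstrap_samples = x$bootstrap_samples,
    seed = x$seed
  )
}

#' Plot the life-years trade-off curve
#'
#' Probability that life-years gained meet or exceed life-years lost,
#' against the candidate survival benefit, with the confidence threshold
#' and break-even benefit marked.
#'
#' @param object A `dpr_tradeoff` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dpr_tradeoff
#' @export
autoplot.dpr_tradeoff <- function(object, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$benefit_pct,
                                    y = .data$prob_gain_exceeds_loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$conf, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "survival benefit (%)",
      y = "P(life-years gained ≥ life-years lost)",
      title = "Life-years break-even analysis"
    ) +
    ggplot2::theme_minimal()
  if (object$reached) {
    p <- p + ggplot2::geom_vline(xintercept = object$break_even_benefit,
                                 linetype = "dotted")
  }
  p
}
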