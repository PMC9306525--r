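# Bounded probability distributions for model inputs.
#
# Every chain input is a conditional probability, so the supported families
# are restricted (by default) to the unit interval. The life-years module
# reuses the same machinery with the unit-interval restriction lifted.

DIST_FAMILIES <- c("point", "uniform", "triangular", "beta", "log_uniform")

#' Distribution specifications for model inputs
#'
#' Constructors for the bounded probability distributions used as model
#' inputs. Each input of the chain model is a conditional probability whose
#' uncertainty is expressed as one of five families: a point mass, a uniform
#' interval, a triangular distribution, a beta distribution, or a
#' log-uniform (uniform on the log scale, useful for order-of-magnitude
#' uncertainty on rare events).
#'
#' @param p Point-mass value.
#' @param a,b Lower and upper support bounds (`a <= b`).
#' @param m Mode of the triangular distribution (`a <= m <= b`).
#' @param shape1,shape2 Positive beta shape parameters.
#' @param description Optional free-text description of the quantity.
#' @param source_note Optional free text recording the provenance of the
#'   values (literature source, placeholder status, ...).
#'
#' @return An object of class `dpr_dist`: a list with elements `family`,
#'   `params`, `description` and `source_note`.
#'
#' @examples
#' dist_point(0.3)
#' dist_uniform(0.1, 0.4)
#' dist_beta(2, 5)
#' @name dist_spec
NULL

new_dist <- function(family, params, description = NULL, source_note = NULL) {
  structure(
    list(
      family = family,
      params = params,
      description = description,
      source_note = source_note
    ),
    class = "dpr_dist"
  )
}

#' @rdname dist_spec
#' @export
dist_point <- function(p, description = NULL, source_note = NULL) {
  new_dist("point", list(p = p), description, source_note)
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(a, b, description = NULL, source_note = NULL) {
  new_dist("uniform", list(a = a, b = b), description, source_note)
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(a, m, b, description = NULL, source_note = NULL) {
  new_dist("triangular", list(a = a, m = m, b = b), description, source_note)
}

#' @rdname dist_spec
#' @export
dist_beta <- function(shape1, shape2, description = NULL, source_note = NULL) {
  new_dist("beta", list(shape1 = shape1, shape2 = shape2),
           description, source_note)
}

#' @rdname dist_spec
#' @export
dist_log_uniform <- function(a, b, description = NULL, source_note = NULL) {
  new_dist("log_uniform", list(a = a, b = b), description, source_note)
}

#' @export
print.dpr_dist <- function(x, ...) {
  pars <- paste(names(x$params), unlist(x$params), sep = " = ",
                collapse = ", ")
  cat("<dpr_dist> ", x$family, "(", pars, ")\n", sep = "")
  if (!is.null(x$description)) cat("  ", x$description, "\n", sep = "")
  invisible(x)
}

#' Validate a distribution specification
#'
#' Checks family-specific parameter constraints. With
#' `unit_interval = TRUE` (the default, appropriate for chain inputs) the
#' support must lie in \[0, 1\]; with `unit_interval = FALSE` only ordering
#' and non-negativity are required (used for the survivor life-years
#' distribution, whose support is measured in years).
#'
#' @param spec A `dpr_dist` object.
#' @param unit_interval Restrict the support to \[0, 1\]?
#' @param id Identifier used in error messages.
#' @return `spec`, invisibly, if valid; otherwise an error naming `id` and
#'   the offending parameter.
#' @export
validate_dist <- function(spec, unit_interval = TRUE, id = "input") {
  if (!inherits(spec, "dpr_dist")) {
    stop("`", id, "` is not a distribution specification", call. = FALSE)
  }
  if (!spec$family %in% DIST_FAMILIES) {
    stop("input `", id, "`: unknown distribution family '", spec$family, "'",
         call. = FALSE)
  }
  p <- spec$params
  bad <- function(par, why) {
    stop("input `", id, "` (", spec$family, "): parameter `", par, "` ", why,
         call. = FALSE)
  }
  num <- function(par) {
    v <- p[[par]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      bad(par, "must be a single finite number")
    }
    v
  }
  switch(spec$family,
    point = {
      v <- num("p")
      if (v < 0) bad("p", "must be non-negative")
      if (unit_interval && v > 1) bad("p", "must lie in [0, 1]")
    },
    uniform = {
      a <- num("a"); b <- num("b")
      if (a > b) bad("a", "must satisfy a <= b")
      if (a < 0) bad("a", "must be non-negative")
      if (unit_interval && b > 1) bad("b", "must lie in [0, 1]")
    },
    triangular = {
      a <- num("a"); m <- num("m"); b <- num("b")
      if (a > m || m > b) bad("m", "must satisfy a <= m <= b")
      if (a < 0) bad("a", "must be non-negative")
      if (unit_interval && b > 1) bad("b", "must lie in [0, 1]")
    },
    beta = {
      s1 <- num("shape1"); s2 <- num("shape2")
      if (s1 <= 0) bad("shape1", "must be > 0")
      if (s2 <= 0) bad("shape2", "must be > 0")
    },
    log_uniform = {
      a <- num("a"); b <- num("b")
      if (a <= 0) bad("a", "must be > 0")
      if (a > b) bad("a", "must satisfy a <= b")
      if (unit_interval && b > 1) bad("b", "must lie in [0, 1]")
    }
  )
  invisible(spec)
}

#' Moments and support of a distribution specification
#'
#' Closed-form mean, variance and support bounds for each family. These are
#' the analytic ground truth against which Monte Carlo output is checked.
#'
#' @param spec A `dpr_dist` object.
#' @return `dist_mean()` and `dist_var()` return a single number;
#'   `dist_support()` returns `c(lower, upper)`.
#' @export
dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    point = p$p,
    uniform = (p$a + p$b) / 2,
    triangular = (p$a + p$m + p$b) / 3,
    beta = p$shape1 / (p$shape1 + p$shape2),
    log_uniform = if (p$a == p$b) p$a else (p$b - p$a) / (log(p$b) - log(p$a))
  )
}

#' @rdname dist_mean
#' @export
dist_var <- function(spec) {
  p <- spec$params
  switch(spec$family,
    point = 0,
    uniform = (p$b - p$a)^2 / 12,
    triangular = (p$a^2 + p$m^2 + p$b^2 -
                    p$a * p$m - p$a * p$b - p$m * p$b) / 18,
    beta = {
      s <- p$shape1 + p$shape2
      p$shape1 * p$shape2 / (s^2 * (s + 1))
    },
    log_uniform = {
      if (p$a == p$b) return(0)
      m2 <- (p$b^2 - p$a^2) / (2 * (log(p$b) - log(p$a)))
      m2 - dist_mean(spec)^2
    }
  )
}

#' @rdname dist_mean
#' @export
dist_support <- function(spec) {
  p <- spec$params
  switch(spec$family,
    point = c(p$p, p$p),
    uniform = c(p$a, p$b),
    triangular = c(p$a, p$b),
    beta = c(0, 1),
    log_uniform = c(p$a, p$b)
  )
}

#' Sample from a distribution specification
#'
#' Draws from the family using the current RNG state, so results are
#' deterministic under `set.seed()`. This is the single sampling routine
#' used by the Monte Carlo engine, the sensitivity estimator and the
#' life-years bootstrap.
#'
#' @param spec A `dpr_dist` object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`, each value inside the declared
#'   support.
#' @examples
#' set.seed(1)
#' sample_input(dist_uniform(0.2, 0.4), 5)
#' @export
sample_input <- function(spec, n = 1L) {
  p <- spec$params
  switch(spec$family,
    point = rep(p$p, n),
    uniform = stats::runif(n, p$a, p$b),
    triangular = r_triangular(n, p$a, p$m, p$b),
    beta = stats::rbeta(n, p$shape1, p$shape2),
    log_uniform = exp(stats::runif(n, log(p$a), log(p$b)))
  )
}

# Inverse-CDF triangular sampler; degenerate edges handled explicitly so a
# zero-width side never divides by zero.
r_triangular <- function(n, a, m, b) {
  if (a == b) return(rep(a, n))
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  lower <- a + sqrt(u * (b - a) * (m - a))
  upper <- b - sqrt((1 - u) * (b - a) * (b - m))
  ifelse(u < fc, lower, upper)
}

# ---- deterministic substreams ------------------------------------------
#
# One root seed; each named input gets its own substream whose seed is a
# deterministic function of (root seed, id). Adding, removing or re-typing
# one input therefore never perturbs the draws of any other input.

str_hash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483629
  h
}

substream_seed <- function(root_seed, key) {
  root <- as.numeric(root_seed) %% 1000003
  as.integer((root * 1103515245 + str_hash(key)) %% 2147483629)
}

# Evaluate fn() under a given seed, restoring the caller's RNG state.
with_stream <- function(seed, fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  fn()
}

# n draws from spec in the substream keyed by (root_seed, key).
draw_stream <- function(spec, n, root_seed, key) {
  with_stream(substream_seed(root_seed, key), function() sample_input(spec, n))
}
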