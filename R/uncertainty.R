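# Deterministic and probabilistic sensitivity analysis. The PSA jointly
# redraws every uncertain parameter from its assigned distribution (beta
# for proportions, gamma for costs and counts, Dirichlet for severity
# splits, the pooled empirical density for elicited transitions), re-runs
# the full model, and summarizes each outcome with an equal-tailed
# percentile Bayesian credibility interval.

#' Parameter distribution specifications
#'
#' Constructors for the distribution families assignable to model
#' parameters in a PSA: `dist_fixed()` (no uncertainty), `dist_beta()`
#' (moment-matched to a mean and concentration, for proportions and
#' probabilities), `dist_gamma()` (moment-matched to a mean and coefficient
#' of variation, for costs and counts), `dist_dirichlet()` (for severity
#' splits; draws a simplex vector), and `dist_empirical()` (resamples a
#' pooled elicited density).
#'
#' @param value Fixed value.
#' @param mean Distribution mean.
#' @param concentration Beta concentration (`shape1 + shape2`).
#' @param cv Gamma coefficient of variation.
#' @param alpha Dirichlet concentration vector.
#' @param density A `pooled_density` from [pool_judgements()].
#' @return A `param_dist` specification.
#' @name param_dist
NULL

#' @rdname param_dist
#' @export
dist_fixed <- function(value) {
  structure(list(family = "fixed", value = value), class = "param_dist")
}

#' @rdname param_dist
#' @export
dist_beta <- function(mean, concentration) {
  check_probability(mean, "mean")
  check_positive(concentration, "concentration")
  structure(list(family = "beta", shape1 = mean * concentration,
                 shape2 = (1 - mean) * concentration),
            class = "param_dist")
}

#' @rdname param_dist
#' @export
dist_gamma <- function(mean, cv) {
  check_positive(mean, "mean")
  check_positive(cv, "cv")
  shape <- 1 / cv^2
  structure(list(family = "gamma", shape = shape, scale = mean / shape),
            class = "param_dist")
}

#' @rdname param_dist
#' @export
dist_dirichlet <- function(alpha) {
  if (any(alpha <= 0)) abort("Dirichlet `alpha` must be positive.")
  structure(list(family = "dirichlet", alpha = alpha), class = "param_dist")
}

#' @rdname param_dist
#' @export
dist_empirical <- function(density) {
  stopifnot(inherits(density, "pooled_density"))
  structure(list(family = "empirical_pooled",
                 support = density$support, weights = density$weight),
            class = "param_dist")
}

param_mean <- function(spec) {
  switch(spec$family,
    fixed = spec$value,
    beta = spec$shape1 / (spec$shape1 + spec$shape2),
    gamma = spec$shape * spec$scale,
    dirichlet = spec$alpha / sum(spec$alpha),
    empirical_pooled = sum(spec$support * spec$weights),
    abort(sprintf("Unknown distribution family '%s'.", spec$family))
  )
}

param_draw <- function(spec) {
  switch(spec$family,
    fixed = spec$value,
    beta = rbeta(1L, spec$shape1, spec$shape2),
    gamma = rgamma(1L, shape = spec$shape, scale = spec$scale),
    dirichlet = {
      x <- rgamma(length(spec$alpha), shape = spec$alpha, scale = 1)
      x / sum(x)
    },
    empirical_pooled = spec$support[
      sample.int(length(spec$support), 1L, prob = spec$weights)],
    abort(sprintf("Unknown distribution family '%s'.", spec$family))
  )
}

#' PSA configuration
#'
#' @param n_iterations Monte Carlo iterations (default 5000).
#' @param credibility_level Credibility-interval level (default 0.95).
#' @param seed Integer seed.
#' @param distribution_map Named list of `param_dist` specifications, one
#'   per uncertain parameter.
#' @return A `psa_config` list.
#' @export
psa_config <- function(n_iterations = 5000L, credibility_level = 0.95,
                       seed = 1L, distribution_map = list()) {
  n_iterations <- check_count(n_iterations, "n_iterations", min = 1L)
  if (credibility_level <= 0 || credibility_level >= 1) {
    abort("`credibility_level` must lie strictly between 0 and 1.")
  }
  seed <- check_count(seed, "seed", min = 0L)
  if (length(distribution_map) > 0L) {
    ok <- vapply(distribution_map, inherits, logical(1L), "param_dist")
    if (is.null(names(distribution_map)) || !all(ok)) {
      abort("`distribution_map` must be a named list of param_dist specs.")
    }
  }
  structure(list(n_iterations = n_iterations,
                 credibility_level = credibility_level,
                 seed = seed, distribution_map = distribution_map),
            class = "psa_config")
}

#' Equal-tailed Bayesian credibility interval
#'
#' Percentile interval of the stored Monte Carlo samples at
#' `(1 - level)/2` and `1 - (1 - level)/2`, using linear interpolation
#' between order statistics (the default quantile convention, type 7).
#'
#' @param samples Numeric vector of Monte Carlo samples.
#' @param level Credibility level in (0, 1) (default 0.95).
#' @return Named vector `c(low, high)`.
#' @examples
#' bci(1:100)
#' @export
bci <- function(samples, level = 0.95) {
  if (length(samples) < 1L || anyNA(samples)) {
    abort("`samples` must be a non-empty numeric vector without NAs.")
  }
  if (level <= 0 || level >= 1) abort("`level` must lie in (0, 1).")
  q <- quantile(samples, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Run a probabilistic sensitivity analysis
#'
#' Evaluates `model_fn` once at the parameter means (the deterministic
#' point estimate) and `n_iterations` times with all parameters jointly
#' redrawn from their distributions. All samples are stored; each outcome
#' is summarized by its point estimate, sample mean and equal-tailed
#' credibility interval. A fixed seed reproduces the result exactly.
#'
#' @param model_fn Function taking a named list of parameter values and
#'   returning a named numeric vector of outcomes.
#' @param config A [psa_config()] whose `distribution_map` covers every
#'   parameter `model_fn` consumes.
#' @return A `psa_result` with elements `summary` (tibble: outcome, point,
#'   mean, bci_low, bci_high), `samples` (tibble: iteration, outcome,
#'   value) and `config`.
#' @examples
#' cfg <- psa_config(n_iterations = 200, seed = 1, distribution_map = list(
#'   price = dist_gamma(mean = 10, cv = 0.3)
#' ))
#' res <- run_psa(function(p) c(cost = 12 * p$price), cfg)
#' tidy(res)
#' @export
run_psa <- function(model_fn, config) {
  stopifnot(is.function(model_fn), inherits(config, "psa_config"))
  dm <- config$distribution_map
  if (length(dm) == 0L) abort("`distribution_map` must not be empty.")
  means <- lapply(dm, param_mean)
  point <- model_fn(means)
  if (is.null(names(point)) || anyNA(names(point))) {
    abort("`model_fn` must return a named numeric vector of outcomes.")
  }
  n <- config$n_iterations
  draws <- matrix(NA_real_, nrow = n, ncol = length(point),
                  dimnames = list(NULL, names(point)))
  set.seed(config$seed)
  for (i in seq_len(n)) {
    params <- lapply(dm, param_draw)
    draws[i, ] <- model_fn(params)
  }
  level <- config$credibility_level
  summary <- tibble::tibble(
    outcome = names(point),
    point = as.numeric(point),
    mean = unname(colMeans(draws)),
    bci_low = unname(apply(draws, 2L, function(s) bci(s, level)[["low"]])),
    bci_high = unname(apply(draws, 2L, function(s) bci(s, level)[["high"]]))
  )
  samples <- tibble::tibble(
    iteration = rep(seq_len(n), times = ncol(draws)),
    outcome = rep(colnames(draws), each = n),
    value = as.numeric(draws)
  )
  structure(list(summary = summary, samples = samples, config = config),
            class = "psa_result")
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the full model three times — at the low, base and high
#' value of one parameter, all other parameters held at base — to isolate
#' that parameter's effect, ceteris paribus.
#'
#' @param model_fn Function taking a named list of parameter values and
#'   returning a named numeric vector of outcomes.
#' @param base_params Named list of base-case parameter values.
#' @param parameter_id Name of the parameter to vary.
#' @param low,high Range; must bracket the base value.
#' @return Tibble: `parameter`, `outcome`, `value_low`, `value_base`,
#'   `value_high`.
#' @export
one_way_sa <- function(model_fn, base_params, parameter_id, low, high) {
  if (!parameter_id %in% names(base_params)) {
    abort(sprintf("Unknown parameter '%s'.", parameter_id))
  }
  base <- base_params[[parameter_id]]
  if (length(base) == 1L && (low > base || high < base)) {
    abort("`low` and `high` must bracket the base value.")
  }
  eval_at <- function(v) {
    p <- base_params
    p[[parameter_id]] <- v
    model_fn(p)
  }
  out_low <- eval_at(low); out_base <- model_fn(base_params)
  out_high <- eval_at(high)
  tibble::tibble(
    parameter = parameter_id,
    outcome = names(out_base),
    value_low = as.numeric(out_low[names(out_base)]),
    value_base = as.numeric(out_base),
    value_high = as.numeric(out_high[names(out_base)])
  )
}

#' Tornado table over several parameters
#'
#' Runs [one_way_sa()] for each row of `ranges` and ranks parameters by
#' the absolute swing they induce on one outcome.
#'
#' @param model_fn,base_params As in [one_way_sa()].
#' @param ranges Tibble with columns `parameter`, `low`, `high`.
#' @param outcome Outcome to rank by (default: the model's first outcome).
#' @return Tibble sorted by descending swing: `parameter`, `value_low`,
#'   `value_base`, `value_high`, `swing`.
#' @export
tornado_table <- function(model_fn, base_params, ranges, outcome = NULL) {
  stopifnot(all(c("parameter", "low", "high") %in% names(ranges)))
  rows <- purrr::pmap_dfr(ranges, function(parameter, low, high) {
    one_way_sa(model_fn, base_params, parameter, low, high)
  })
  if (is.null(outcome)) outcome <- rows$outcome[1L]
  rows |>
    dplyr::filter(.data$outcome == !!outcome) |>
    dplyr::mutate(swing = abs(.data$value_high - .data$value_low)) |>
    dplyr::arrange(dplyr::desc(.data$swing))
}

# broom-style accessors ----------------------------------------------------

#' @export
tidy.psa_result <- function(x, ...) {
  x$summary
}

#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$config$n_iterations,
    credibility_level = x$config$credibility_level,
    seed = x$config$seed,
    n_outcomes = nrow(x$summary),
    n_parameters = length(x$config$distribution_map)
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$config$n_iterations, "iterations,",
      nrow(x$summary), "outcomes\n")
  print(x$summary)
  invisible(x)
}
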