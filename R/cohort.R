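# Markov cohort machinery: prevalent cohorts, initial allocation by severity,
# and the monthly cohort trace with an absorbing death state.

#' Convert an annual probability to a monthly probability
#'
#' Assumes the event occurs at a constant instantaneous rate within the
#' year, so the monthly probability is `1 - (1 - p_annual)^(1/12)`. Use
#' [mortality_parameter()] when the input is a crude death rate per 1000
#' rather than an annual probability.
#'
#' @param p_annual Annual probability in \[0, 1\]. Vectorized.
#' @return Monthly probability, same length as `p_annual`.
#' @examples
#' annual_to_monthly_prob(0.12)
#' @export
annual_to_monthly_prob <- function(p_annual) {
  check_probability(p_annual, "p_annual", allow_vector = TRUE)
  1 - (1 - p_annual)^(1 / 12)
}

#' Background mortality parameter
#'
#' The published annual mortality figure (deaths per 1000 inhabitants per
#' year) is a crude death *rate*, so the monthly death probability is
#' derived by treating it as the constant instantaneous rate directly:
#' `1 - exp(-(annual_per_1000 / 1000) / 12)`. At the default 5.1 per 1000
#' this gives 0.42 per 1000 per month (2-decimal rounding). For inputs
#' that are annual probabilities rather than rates, use
#' [annual_to_monthly_prob()].
#'
#' @param annual_per_1000 Annual all-cause deaths per 1000 inhabitants
#'   (default 5.1).
#' @return A list with `annual_per_1000` and the derived
#'   `monthly_probability`.
#' @examples
#' round(mortality_parameter()$monthly_probability * 1000, 2)
#' @export
mortality_parameter <- function(annual_per_1000 = 5.1) {
  if (!is.numeric(annual_per_1000) || length(annual_per_1000) != 1L ||
      is.na(annual_per_1000) || annual_per_1000 < 0 || annual_per_1000 > 1000) {
    abort("`annual_per_1000` must be a single number in [0, 1000].")
  }
  list(
    annual_per_1000 = annual_per_1000,
    monthly_probability = 1 - exp(-(annual_per_1000 / 1000) / 12)
  )
}

#' Construct a pathology cohort
#'
#' Bundles one pathology's prevalent count, its severity split at model entry
#' (mild/moderate/severe proportions summing to 1), and the fraction of each
#' severity stratum that holds an actual diagnosis. Only diagnosed patients
#' enter the cost-incurring modelled cohort; undiagnosed patients are tracked
#' for prevalence reporting.
#'
#' @param pathology Label for the pathology.
#' @param prevalent_count Non-negative prevalent case count.
#' @param severity_split Length-3 proportions (mild, moderate, severe)
#'   summing to 1.
#' @param diagnosed_fractions Length-3 proportions in \[0, 1\]; default all 1
#'   (the base-case assumption that every prevalent case is diagnosed).
#' @return A `pathology_cohort` list.
#' @examples
#' pathology_cohort("lbp", 1000, c(0.5, 0.3, 0.2))
#' @export
pathology_cohort <- function(pathology, prevalent_count, severity_split,
                             diagnosed_fractions = c(1, 1, 1)) {
  if (!is.character(pathology) || length(pathology) != 1L) {
    abort("`pathology` must be a single label.")
  }
  if (!is.numeric(prevalent_count) || length(prevalent_count) != 1L ||
      is.na(prevalent_count) || prevalent_count < 0) {
    abort("`prevalent_count` must be a non-negative number.")
  }
  check_probability(severity_split, "severity_split", allow_vector = TRUE)
  if (length(severity_split) != 3L) {
    abort("`severity_split` must have length 3 (mild, moderate, severe).")
  }
  if (abs(sum(severity_split) - 1) > 1e-9) {
    abort("`severity_split` must sum to 1 (within 1e-9).")
  }
  check_probability(diagnosed_fractions, "diagnosed_fractions",
                    allow_vector = TRUE)
  if (length(diagnosed_fractions) != 3L) {
    abort("`diagnosed_fractions` must have length 3.")
  }
  structure(
    list(
      pathology = pathology,
      prevalent_count = prevalent_count,
      severity_split = setNames(severity_split, LIVING_STATES),
      diagnosed_fractions = setNames(diagnosed_fractions, LIVING_STATES)
    ),
    class = "pathology_cohort"
  )
}

#' Initial occupancy vector of a cohort
#'
#' Allocates the diagnosed prevalent cases to the three living states as
#' `prevalent_count * severity_split * diagnosed_fraction`; death starts at
#' zero. The undiagnosed remainder is excluded from the modelled
#' (cost-incurring) cohort and reported in the `undiagnosed` attribute.
#'
#' @param cohort A [pathology_cohort()].
#' @return Named numeric vector over (mild, moderate, severe, dead), with
#'   attribute `undiagnosed` giving the excluded count per living state.
#' @examples
#' initial_state_vector(pathology_cohort("lbp", 1000, c(0.5, 0.3, 0.2)))
#' @export
initial_state_vector <- function(cohort) {
  stopifnot(inherits(cohort, "pathology_cohort"))
  by_state <- cohort$prevalent_count * cohort$severity_split
  modelled <- by_state * cohort$diagnosed_fractions
  out <- c(modelled, dead = 0)
  attr(out, "undiagnosed") <- by_state - modelled
  out
}

#' Build a transition-matrix object
#'
#' Validates a 4x4 row-stochastic matrix over (mild, moderate, severe, dead)
#' with an absorbing death row.
#'
#' @param entries 4x4 numeric matrix, rows = origin state, columns =
#'   destination state, in the order mild, moderate, severe, dead.
#' @return The matrix with class `transition_matrix`.
#' @export
transition_matrix <- function(entries) {
  entries <- as.matrix(entries)
  if (!all(dim(entries) == c(4L, 4L))) {
    abort("`entries` must be a 4x4 matrix.")
  }
  if (anyNA(entries) || any(entries < -1e-12) || any(entries > 1 + 1e-12)) {
    abort("Transition probabilities must lie in [0, 1].")
  }
  entries <- pmin(pmax(entries, 0), 1)
  if (any(abs(rowSums(entries) - 1) > 1e-9)) {
    abort("Every transition-matrix row must sum to 1 (within 1e-9).")
  }
  if (!isTRUE(all.equal(unname(entries[4, ]), c(0, 0, 0, 1), tolerance = 1e-9))) {
    abort("The death row must be absorbing: (0, 0, 0, 1).")
  }
  dimnames(entries) <- list(STATES, STATES)
  class(entries) <- c("transition_matrix", class(entries))
  entries
}

#' Run the monthly Markov cohort trace
#'
#' Propagates the occupancy vector through `horizon_cycles` one-month cycles
#' under constant transition probabilities: `occupancy(t+1) = occupancy(t) %*%
#' matrix`. Total population (including the death state) is conserved every
#' cycle.
#'
#' @param initial Named occupancy over (mild, moderate, severe, dead), e.g.
#'   from [initial_state_vector()].
#' @param matrix A [transition_matrix()] (or a plain 4x4 matrix, validated).
#' @param horizon_cycles Number of cycles (default 12, the one-year horizon).
#' @return A `cohort_trace` tibble with columns `cycle` (0..horizon),
#'   `state`, `occupancy`.
#' @examples
#' m <- transition_matrix(diag(4))
#' run_cohort(c(mild = 10, moderate = 5, severe = 1, dead = 0), m, 3)
#' @export
run_cohort <- function(initial, matrix, horizon_cycles = 12L) {
  if (!inherits(matrix, "transition_matrix")) matrix <- transition_matrix(matrix)
  horizon_cycles <- check_count(horizon_cycles, "horizon_cycles", min = 1L)
  if (length(initial) != 4L || anyNA(initial) || any(initial < 0)) {
    abort("`initial` must be 4 non-negative occupancies (mild, moderate, severe, dead).")
  }
  occ <- matrix(0, nrow = horizon_cycles + 1L, ncol = 4L,
                dimnames = list(NULL, STATES))
  occ[1L, ] <- as.numeric(initial)
  m <- unclass(matrix)
  for (t in seq_len(horizon_cycles)) {
    occ[t + 1L, ] <- occ[t, ] %*% m
  }
  out <- tibble::tibble(
    cycle = rep(0:horizon_cycles, times = 4L),
    state = factor(rep(STATES, each = horizon_cycles + 1L), levels = STATES),
    occupancy = as.numeric(occ)
  )
  class(out) <- c("cohort_trace", class(out))
  attr(out, "cycle_length_months") <- 1L
  attr(out, "horizon_cycles") <- horizon_cycles
  out
}

# Wide (cycle x state) matrix view of a trace; used by the costing layer.
trace_matrix <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  h <- attr(trace, "horizon_cycles")
  matrix(trace$occupancy, nrow = h + 1L, ncol = 4L,
         dimnames = list(NULL, STATES))
}

#' Apply the reduced-diagnosis scenario to a set of cohorts
#'
#' Implements the sensitivity scenario in which a fraction of mild and
#' moderate prevalent cases has never been diagnosed (and therefore incurs
#' no management cost). Severe cases are always fully diagnosed.
#'
#' @param cohorts A list of [pathology_cohort()] objects.
#' @param mild_undx Undiagnosed proportion among mild cases (default 0.5).
#' @param moderate_undx Undiagnosed proportion among moderate cases
#'   (default 0.25).
#' @return The cohorts with `diagnosed_fractions` set to
#'   `(1 - mild_undx, 1 - moderate_undx, 1)`.
#' @export
apply_undiagnosed_scenario <- function(cohorts, mild_undx = 0.5,
                                       moderate_undx = 0.25) {
  check_probability(mild_undx, "mild_undx")
  check_probability(moderate_undx, "moderate_undx")
  lapply(cohorts, function(ch) {
    stopifnot(inherits(ch, "pathology_cohort"))
    ch$diagnosed_fractions <- setNames(
      c(1 - mild_undx, 1 - moderate_undx, 1), LIVING_STATES)
    ch
  })
}

#' Percent decrease between a base and a scenario total
#'
#' @param base Base-case total.
#' @param scenario Scenario total.
#' @return `(1 - scenario / base) * 100`, in percent.
#' @examples
#' percent_decrease(1387.2, 1095.89)
#' @export
percent_decrease <- function(base, scenario) {
  check_positive(base, "base")
  (1 - scenario / base) * 100
}

#' @export
tidy.cohort_trace <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.cohort_trace <- function(x, ...) {
  h <- attr(x, "horizon_cycles")
  start <- sum(x$occupancy[x$cycle == 0])
  end_dead <- x$occupancy[x$cycle == h & x$state == "dead"]
  tibble::tibble(
    horizon_cycles = h,
    initial_cohort = start,
    deaths = end_dead,
    conservation_error = max(abs(
      tapply(x$occupancy, x$cycle, sum) - start))
  )
}
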