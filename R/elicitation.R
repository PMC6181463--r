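# Pooling of discretized expert probability judgements (linear opinion pool)
# and assembly of the monthly transition matrix.
#
# A judgement panel is a long tibble with columns `expert_id`, `bin_midpoint`,
# `weight`: each expert distributes weight 1 over a shared grid of candidate
# probability values. Pooling keeps every (expert, bin) option as a support
# point — a 13-expert x 21-bin panel pools to 273 options — so the pooled
# object preserves the full empirical uncertainty revealed by the panel.

validate_panel <- function(judgements) {
  required <- c("expert_id", "bin_midpoint", "weight")
  if (!is.data.frame(judgements) || !all(required %in% names(judgements))) {
    abort("`judgements` must have columns expert_id, bin_midpoint, weight.")
  }
  if (nrow(judgements) == 0L) {
    abort("`judgements` must contain at least one expert judgement.")
  }
  split_j <- split(judgements, judgements$expert_id)
  grids <- lapply(split_j, function(d) d$bin_midpoint)
  ref <- grids[[1L]]
  if (any(diff(ref) <= 0)) {
    abort("The probability grid must be strictly increasing.")
  }
  check_probability(ref, "bin_midpoint", allow_vector = TRUE)
  same <- vapply(grids, function(g) {
    length(g) == length(ref) && max(abs(g - ref)) < 1e-12
  }, logical(1L))
  if (!all(same)) {
    abort("All experts must answer on the same probability grid.")
  }
  sums <- vapply(split_j, function(d) sum(d$weight), numeric(1L))
  if (any(judgements$weight < 0) || any(abs(sums - 1) > 1e-9)) {
    abort("Each expert's weights must be non-negative and sum to 1 (within 1e-9).")
  }
  split_j
}

#' Pool expert judgements into an empirical density
#'
#' Linear opinion pool: the pooled weight of every (expert, bin) option is
#' the expert's weight on that bin times the expert's pooling weight
#' (equal across experts unless `expert_weights` is supplied). All options
#' are retained as support points, so `n_options = n_experts * n_bins`.
#'
#' @param judgements Long tibble with columns `expert_id`, `bin_midpoint`,
#'   `weight`; one row per (expert, bin).
#' @param expert_weights Optional non-negative pooling weights, one per
#'   expert (in the order experts first appear), summing to 1. Default:
#'   equal weights.
#' @return A `pooled_density` tibble with columns `expert_id`, `support`,
#'   `weight` and attributes `n_experts`, `n_options`.
#' @examples
#' panel <- generate_expert_panel(0.3, n_experts = 13, seed = 1)
#' pooled <- pool_judgements(panel)
#' attr(pooled, "n_options")
#' elicited_mean(pooled)
#' @export
pool_judgements <- function(judgements, expert_weights = NULL) {
  split_j <- validate_panel(judgements)
  n_experts <- length(split_j)
  if (is.null(expert_weights)) {
    expert_weights <- rep(1 / n_experts, n_experts)
  }
  if (length(expert_weights) != n_experts || any(expert_weights < 0) ||
      abs(sum(expert_weights) - 1) > 1e-9) {
    abort("`expert_weights` must be non-negative, one per expert, summing to 1.")
  }
  pooled <- purrr::map2_dfr(split_j, expert_weights, function(d, w) {
    tibble::tibble(
      expert_id = d$expert_id,
      support = d$bin_midpoint,
      weight = d$weight * w
    )
  })
  structure(
    pooled,
    n_experts = n_experts,
    n_options = nrow(pooled),
    class = c("pooled_density", class(tibble::tibble()))
  )
}

#' Expected value of a pooled elicited density
#'
#' @param density A `pooled_density` from [pool_judgements()].
#' @return The probability-scale mean, `sum(support * weight)`.
#' @export
elicited_mean <- function(density) {
  stopifnot(inherits(density, "pooled_density"))
  sum(density$support * density$weight)
}

#' Sample transition probabilities from a pooled density
#'
#' Draws support points with probability equal to their pooled weight —
#' the probabilistic-sensitivity-analysis sampler that resamples the
#' elicited empirical distribution directly rather than a parametric fit.
#'
#' @param density A `pooled_density`.
#' @param n Number of draws (default 1).
#' @return Numeric vector of sampled probabilities.
#' @export
sample_transition_prob <- function(density, n = 1L) {
  stopifnot(inherits(density, "pooled_density"))
  n <- check_count(n, "n", min = 1L)
  idx <- sample.int(nrow(density), size = n, replace = TRUE,
                    prob = density$weight)
  density$support[idx]
}

# Transition labels used throughout: "mild_to_moderate", ... The six
# off-diagonal living transitions are elicited; stay probabilities are
# complements unless given explicitly.
transition_labels <- function(include_diagonal = FALSE) {
  pairs <- expand.grid(from = LIVING_STATES, to = LIVING_STATES,
                       stringsAsFactors = FALSE)
  if (!include_diagonal) pairs <- pairs[pairs$from != pairs$to, ]
  paste(pairs$from, pairs$to, sep = "_to_")
}

elicited_value <- function(x, mode) {
  if (inherits(x, "pooled_density")) {
    if (mode == "mean") elicited_mean(x) else sample_transition_prob(x, 1L)
  } else {
    check_probability(x, "elicited probability")
    as.numeric(x)
  }
}

#' Assemble the monthly 4-state transition matrix
#'
#' Combines elicited living-state transition probabilities with background
#' mortality. Elicited entries are taken either at their pooled means
#' (`mode = "mean"`) or redrawn from their pooled densities
#' (`mode = "sample"`, for the PSA). Any missing diagonal (stay) entry is
#' the complement of its row's off-diagonal entries; rows are renormalized
#' to sum to 1 (independently elicited questions need not cohere exactly),
#' then mortality competes multiplicatively: living-to-living entries are
#' scaled by `1 - monthly_death` and the death column of every living row
#' is `monthly_death`. The death row is absorbing.
#'
#' @param elicited Named list mapping transition labels
#'   (`"mild_to_moderate"`, ...) to a `pooled_density` or a fixed
#'   probability. The six off-diagonal labels are required; diagonal labels
#'   are optional.
#' @param monthly_death Monthly probability of death from other causes.
#' @param mode `"mean"` (default) or `"sample"`.
#' @return A [transition_matrix()].
#' @examples
#' probs <- list(
#'   mild_to_moderate = 0.15, mild_to_severe = 0.03,
#'   moderate_to_mild = 0.12, moderate_to_severe = 0.10,
#'   severe_to_mild = 0.03, severe_to_moderate = 0.12
#' )
#' build_transition_matrix(probs, monthly_death = 0.00042)
#' @export
build_transition_matrix <- function(elicited, monthly_death,
                                    mode = c("mean", "sample")) {
  mode <- match.arg(mode)
  check_probability(monthly_death, "monthly_death")
  needed <- transition_labels()
  missing <- setdiff(needed, names(elicited))
  if (length(missing) > 0L) {
    abort(paste0("Missing elicited transitions: ",
                 paste(missing, collapse = ", ")))
  }
  living <- matrix(NA_real_, 3L, 3L,
                   dimnames = list(LIVING_STATES, LIVING_STATES))
  for (from in LIVING_STATES) {
    for (to in LIVING_STATES) {
      lab <- paste(from, to, sep = "_to_")
      if (lab %in% names(elicited)) {
        living[from, to] <- elicited_value(elicited[[lab]], mode)
      }
    }
    if (is.na(living[from, from])) {
      off <- sum(living[from, setdiff(LIVING_STATES, from)])
      if (off > 1 + 1e-9) {
        abort(sprintf(
          "Off-diagonal transitions out of '%s' sum to %.4f > 1; cannot take the stay probability as the complement.",
          from, off))
      }
      living[from, from] <- max(0, 1 - off)
    }
  }
  if (any(living < 0)) abort("Transition probabilities must be non-negative.")
  living <- living / rowSums(living)  # coherence renormalization
  m <- matrix(0, 4L, 4L, dimnames = list(STATES, STATES))
  m[1:3, 1:3] <- living * (1 - monthly_death)
  m[1:3, 4L] <- monthly_death
  m[4L, 4L] <- 1
  transition_matrix(m)
}
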