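# Cost-basket valuation and accumulation of expected direct costs over the
# cohort trace. Baskets are tidy tables of resources with unit prices in
# 2015 Chilean pesos (CLP); USD conversion uses the purchasing-power-parity
# rate.

COST_CATEGORIES <- c("medical_visit", "pharmacological", "physiotherapy",
                     "hospitalization")

#' Currency configuration
#'
#' @param clp_per_usd Chilean pesos per US dollar (default 394.35, the 2015
#'   purchasing power parity).
#' @param reference_year Price year (default 2015).
#' @return A `currency_config` list.
#' @export
currency_config <- function(clp_per_usd = 394.35, reference_year = 2015L) {
  check_positive(clp_per_usd, "clp_per_usd")
  structure(list(clp_per_usd = clp_per_usd,
                 reference_year = as.integer(reference_year)),
            class = "currency_config")
}

#' Convert Chilean pesos to US dollars
#'
#' @param amount_clp Amount(s) in CLP.
#' @param fx A [currency_config()].
#' @return Amount(s) in USD.
#' @examples
#' to_usd(394.35)
#' @export
to_usd <- function(amount_clp, fx = currency_config()) {
  if (!inherits(fx, "currency_config")) abort("`fx` must be a currency_config().")
  amount_clp / fx$clp_per_usd
}

validate_basket <- function(basket) {
  required <- c("state", "resource", "category", "unit_price_clp",
                "monthly_quantity", "user_fraction")
  if (!is.data.frame(basket) || !all(required %in% names(basket))) {
    abort(paste0("A cost basket needs columns: ",
                 paste(required, collapse = ", ")))
  }
  if (nrow(basket) > 0L) {
    bad_cat <- setdiff(unique(basket$category), COST_CATEGORIES)
    if (length(bad_cat) > 0L) {
      abort(paste0("Unknown cost categories: ",
                   paste(bad_cat, collapse = ", ")))
    }
    if (any(basket$unit_price_clp < 0) || any(basket$monthly_quantity < 0)) {
      abort("Unit prices and monthly quantities must be non-negative.")
    }
    check_probability(basket$user_fraction, "user_fraction",
                      allow_vector = TRUE)
  }
  invisible(basket)
}

#' Per-patient monthly cost of a basket
#'
#' Values a basket as `sum(unit_price * monthly_quantity * user_fraction)`
#' over its items: the expected monthly management cost of one patient
#' occupying the basket's state.
#'
#' @param basket Basket tibble (see [reference_baskets()] for the schema).
#' @return Cost per patient-month in CLP.
#' @examples
#' ref <- reference_baskets()
#' state_monthly_cost(dplyr::filter(ref, state == "severe"))
#' @export
state_monthly_cost <- function(basket) {
  validate_basket(basket)
  if (nrow(basket) == 0L) return(0)
  sum(basket$unit_price_clp * basket$monthly_quantity * basket$user_fraction)
}

#' Per-state monthly costs of a basket table
#'
#' Convenience wrapper summarizing a (possibly multi-state, multi-pathology)
#' basket table into per-group monthly costs.
#'
#' @param baskets Basket tibble, optionally with a `pathology` column.
#' @param fx A [currency_config()] used to add a USD column.
#' @return Tibble with one row per (pathology,) state: `monthly_cost_clp`,
#'   `monthly_cost_usd`.
#' @export
state_cost_table <- function(baskets, fx = currency_config()) {
  validate_basket(baskets)
  keys <- intersect(c("pathology", "state"), names(baskets))
  baskets |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      monthly_cost_clp = sum(.data$unit_price_clp * .data$monthly_quantity *
                               .data$user_fraction),
      .groups = "drop"
    ) |>
    dplyr::mutate(monthly_cost_usd = to_usd(.data$monthly_cost_clp, fx))
}

#' Expected direct cost over a cohort trace
#'
#' Accumulates `occupancy x state cost` over cycles 0..T-1 (costs accrue on
#' the state occupied at the start of each cycle; no half-cycle correction,
#' no discounting over the one-year horizon). The death state carries no
#' cost.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param state_costs Named numeric: cost per patient-month (CLP) for each
#'   living state (`mild`, `moderate`, `severe`).
#' @return Total expected cost in CLP.
#' @examples
#' m <- transition_matrix(diag(4))
#' tr <- run_cohort(c(mild = 100, moderate = 0, severe = 0, dead = 0), m, 12)
#' expected_direct_cost(tr, c(mild = 1, moderate = 0, severe = 0))
#' @export
expected_direct_cost <- function(trace, state_costs) {
  stopifnot(inherits(trace, "cohort_trace"))
  missing <- setdiff(LIVING_STATES, names(state_costs))
  if (length(missing) > 0L) {
    abort(paste0("`state_costs` is missing states: ",
                 paste(missing, collapse = ", ")))
  }
  occ <- trace_matrix(trace)
  h <- attr(trace, "horizon_cycles")
  start_occ <- occ[seq_len(h), LIVING_STATES, drop = FALSE]
  sum(start_occ %*% as.numeric(state_costs[LIVING_STATES]))
}

#' Cost shares by resource category
#'
#' Decomposes the expected direct cost into the four resource categories
#' (medical visits, pharmacological treatment, physiotherapy,
#' hospitalization), weighting each basket item by the patient-months
#' accumulated in its state.
#'
#' @param baskets Basket tibble with a `pathology` column.
#' @param traces Named list of `cohort_trace` objects, one per pathology.
#' @return Tibble: `category`, `cost_clp`, `share` (shares sum to 1).
#' @export
cost_breakdown <- function(baskets, traces) {
  validate_basket(baskets)
  if (!"pathology" %in% names(baskets)) {
    abort("`baskets` must have a `pathology` column.")
  }
  pm <- purrr::imap_dfr(traces, function(tr, p) {
    occ <- trace_matrix(tr)
    h <- attr(tr, "horizon_cycles")
    tibble::tibble(
      pathology = p, state = LIVING_STATES,
      patient_months = colSums(occ[seq_len(h), LIVING_STATES, drop = FALSE])
    )
  })
  out <- baskets |>
    dplyr::mutate(item_cost = .data$unit_price_clp * .data$monthly_quantity *
                    .data$user_fraction) |>
    dplyr::inner_join(pm, by = c("pathology", "state")) |>
    dplyr::mutate(category = factor(.data$category, levels = COST_CATEGORIES)) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(cost_clp = sum(.data$item_cost * .data$patient_months),
                     .groups = "drop") |>
    tidyr::complete(category = factor(COST_CATEGORIES, levels = COST_CATEGORIES),
                    fill = list(cost_clp = 0))
  total <- sum(out$cost_clp)
  out$share <- if (total > 0) out$cost_clp / total else rep(0, nrow(out))
  out$category <- as.character(out$category)
  out
}
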