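# Burden-of-disease and productivity calculators: years lived with
# disability restricted to the pain domain, depression attributable to
# chronic pain via the population attributable fraction, anxiety
# prevalence and cost, and human-capital productivity loss.

#' Years lived with disability (pain domain)
#'
#' `cases x duration x disability_weight x pain_domain_fraction`. The
#' disability weight ranges from 0 (perfect health) to 1 (health loss
#' equivalent to death); the pain-domain fraction restricts the weight to
#' the share of disability driven by pain itself. By default the package
#' uses prevalent-year cases with a one-year duration (annualized YLD); an
#' incidence-times-duration reading uses the same arithmetic with incident
#' cases and the disease duration in years.
#'
#' @param case_count Case count (vectorized).
#' @param duration_years Duration in years (> 0).
#' @param disability_weight Disability weight in \[0, 1\].
#' @param pain_domain_fraction Pain-domain adjustment in \[0, 1\]
#'   (default 1).
#' @return YLDs.
#' @examples
#' yld(1000, 1, 0.2)
#' @export
yld <- function(case_count, duration_years, disability_weight,
                pain_domain_fraction = 1) {
  if (any(case_count < 0)) abort("`case_count` must be non-negative.")
  if (any(duration_years <= 0)) abort("`duration_years` must be positive.")
  check_probability(disability_weight, "disability_weight",
                    allow_vector = TRUE)
  check_probability(pain_domain_fraction, "pain_domain_fraction",
                    allow_vector = TRUE)
  case_count * duration_years * disability_weight * pain_domain_fraction
}

#' Population attributable fraction (Levin's formula)
#'
#' `p(RR - 1) / (1 + p(RR - 1))`: the proportion of cases of an outcome
#' (here, depression) avoidable if the exposure (chronic pain) were absent,
#' from the exposure prevalence `p` and the relative risk `RR`.
#'
#' @param exposure_prevalence Exposure prevalence in \[0, 1\] (vectorized).
#' @param relative_risk Relative risk (>= 0, vectorized).
#' @return The attributable fraction; 0 when `RR = 1`, below 1 for finite
#'   `RR`.
#' @examples
#' paf(0.2, 3)
#' @export
paf <- function(exposure_prevalence, relative_risk) {
  check_probability(exposure_prevalence, "exposure_prevalence",
                    allow_vector = TRUE)
  if (any(relative_risk < 0)) abort("`relative_risk` must be >= 0.")
  num <- exposure_prevalence * (relative_risk - 1)
  denom <- 1 + num
  if (any(denom <= 0)) {
    abort(paste0(
      "Levin denominator 1 + p(RR - 1) is non-positive; a protective RR ",
      "this strong at this prevalence is outside the attributable-fraction ",
      "definition. Check the exposure prevalence and relative risk."))
  }
  num / denom
}

#' Depression cases attributable to chronic pain
#'
#' Applies the attributable fraction to the depression cases in the
#' population, restricted to patients in moderate or severe pain: mild
#' pain is assumed to carry depression associated with, but not
#' attributable to, chronic pain, so mild-state patients are excluded
#' through the state-share gate.
#'
#' @param paf_value Attributable fraction in \[0, 1).
#' @param depression_cases Depression case count in the population (or
#'   already-eligible cases if `state_shares` is omitted).
#' @param state_shares Optional named shares over `mild`, `moderate`,
#'   `severe` (summing to at most 1); eligibility is the moderate + severe
#'   share. Default: all cases eligible.
#' @return Attributable case count.
#' @examples
#' attributable_depression(0.25, 400)
#' attributable_depression(0.25, 400, c(mild = 1, moderate = 0, severe = 0))
#' @export
attributable_depression <- function(paf_value, depression_cases,
                                    state_shares = NULL) {
  check_probability(paf_value, "paf_value")
  if (any(depression_cases < 0)) abort("`depression_cases` must be non-negative.")
  gate <- 1
  if (!is.null(state_shares)) {
    check_probability(state_shares, "state_shares", allow_vector = TRUE)
    missing <- setdiff(LIVING_STATES, names(state_shares))
    if (length(missing) > 0L) {
      abort(paste0("`state_shares` is missing states: ",
                   paste(missing, collapse = ", ")))
    }
    gate <- sum(state_shares[c("moderate", "severe")])
  }
  paf_value * depression_cases * gate
}

#' Productivity loss under the human-capital approach
#'
#' Societal loss is the medical-leave time valued at the average market
#' wage: `episodes x days x daily_wage`. The health-system cost is the
#' fraction of leave days the system actually pays. Pathologies flagged as
#' structural zeros (myofascial syndrome, which has no ICD-10 code and so
#' cannot be identified in leave records) return `NA` losses with
#' `structural_zero = TRUE`, distinguishing "not estimable" from a
#' computed zero.
#'
#' @param params Tibble with columns `pathology`, `leave_episodes`,
#'   `mean_days_per_episode`, `daily_wage_usd`, `system_paid_fraction`
#'   and optionally `structural_zero`.
#' @return Tibble: `pathology`, `societal_loss_usd`,
#'   `health_system_cost_usd`, `structural_zero`.
#' @examples
#' productivity_loss(tibble::tibble(
#'   pathology = "lbp", leave_episodes = 1, mean_days_per_episode = 10,
#'   daily_wage_usd = 50, system_paid_fraction = 0.8
#' ))
#' @export
productivity_loss <- function(params) {
  required <- c("pathology", "leave_episodes", "mean_days_per_episode",
                "daily_wage_usd", "system_paid_fraction")
  if (!is.data.frame(params) || !all(required %in% names(params))) {
    abort(paste0("`params` needs columns: ", paste(required, collapse = ", ")))
  }
  if (!"structural_zero" %in% names(params)) params$structural_zero <- FALSE
  ok <- !params$structural_zero
  num_cols <- c("leave_episodes", "mean_days_per_episode", "daily_wage_usd")
  for (cl in num_cols) {
    if (any(params[[cl]][ok] < 0, na.rm = FALSE)) {
      abort(sprintf("`%s` must be non-negative.", cl))
    }
  }
  check_probability(params$system_paid_fraction[ok], "system_paid_fraction",
                    allow_vector = TRUE)
  societal <- params$leave_episodes * params$mean_days_per_episode *
    params$daily_wage_usd
  societal[!ok] <- NA_real_
  tibble::tibble(
    pathology = params$pathology,
    societal_loss_usd = societal,
    health_system_cost_usd = societal * params$system_paid_fraction,
    structural_zero = params$structural_zero
  )
}
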