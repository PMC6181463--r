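# End-to-end orchestration: bundle validation, scenario policy, the shared
# model evaluator behind both the deterministic run and the PSA, and the
# report writer. One code path computes every total, so the PSA point
# estimate at parameter means equals the deterministic result exactly.

#' Scenario configuration
#'
#' Policy settings layered on top of an input bundle: the time horizon,
#' whether the reduced-diagnosis scenario is active, how the
#' myofascial-syndrome severity split is read from the specialist
#' consultation fractions, currency, PSA settings, and an optional GDP
#' denominator for reporting total cost as a GDP share.
#'
#' @param scenario `"base"` (all prevalent cases diagnosed) or
#'   `"undiagnosed"` (a fraction of mild/moderate cases never diagnosed
#'   and therefore unmanaged).
#' @param horizon_cycles Number of monthly cycles (default 12).
#' @param undiagnosed_fractions Named proportions `c(mild = , moderate = )`
#'   used when `scenario = "undiagnosed"` (default 0.5 and 0.25).
#' @param mfs_split_mode `"normalized_consult"` (the consultation fractions,
#'   normalized, are the myofascial-syndrome severity split — the default
#'   reading) or `"multiplier"` (the generated split is kept and the
#'   consultation fractions act as per-state cost-incurring multipliers).
#' @param consult_fractions Specialist consultation fractions by severity
#'   (default `c(0.075, 0.35, 0.60)`).
#' @param currency A [currency_config()].
#' @param psa A [psa_config()]; its `distribution_map` is filled from the
#'   bundle at run time.
#' @param gdp_denominator_usd Optional national GDP (USD) to report total
#'   cost as a GDP share.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("base", "undiagnosed"),
                            horizon_cycles = 12L,
                            undiagnosed_fractions = c(mild = 0.5, moderate = 0.25),
                            mfs_split_mode = c("normalized_consult", "multiplier"),
                            consult_fractions = c(mild = 0.075, moderate = 0.35,
                                                  severe = 0.60),
                            currency = currency_config(),
                            psa = psa_config(),
                            gdp_denominator_usd = NULL) {
  scenario <- match.arg(scenario)
  mfs_split_mode <- match.arg(mfs_split_mode)
  horizon_cycles <- check_count(horizon_cycles, "horizon_cycles", min = 1L)
  check_probability(unname(undiagnosed_fractions), "undiagnosed_fractions",
                    allow_vector = TRUE)
  check_probability(unname(consult_fractions), "consult_fractions",
                    allow_vector = TRUE)
  if (!is.null(gdp_denominator_usd)) check_positive(gdp_denominator_usd,
                                                    "gdp_denominator_usd")
  structure(
    list(scenario = scenario, horizon_cycles = horizon_cycles,
         undiagnosed_fractions = undiagnosed_fractions,
         mfs_split_mode = mfs_split_mode,
         consult_fractions = consult_fractions,
         currency = currency, psa = psa,
         gdp_denominator_usd = gdp_denominator_usd),
    class = "scenario_config"
  )
}

#' Validate a model input bundle
#'
#' Checks every structural invariant of the bundle — severity splits
#' summing to 1, probabilities and proportions in range, elicitation
#' histograms normalized on a shared increasing grid, non-negative prices
#' and quantities, known cost categories — and reports all violations, not
#' just the first.
#'
#' @param bundle A `pain_bundle` or a path to a directory written by
#'   [write_bundle()].
#' @return A tibble of violations (`component`, `where`, `message`); zero
#'   rows means the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "pain_bundle"))
  v <- list()
  add <- function(component, where, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      component = component, where = where, message = message)
  }

  p <- bundle$pathologies
  for (i in seq_len(nrow(p))) {
    split <- c(p$split_mild[i], p$split_moderate[i], p$split_severe[i])
    if (any(split < 0) || abs(sum(split) - 1) > 1e-9) {
      add("pathologies", p$pathology[i],
          sprintf("severity split sums to %.6f, expected 1", sum(split)))
    }
    if (is.na(p$prevalent_count[i]) || p$prevalent_count[i] < 0) {
      add("pathologies", p$pathology[i], "prevalent_count must be >= 0")
    }
    if (p$prevalence[i] < 0 || p$prevalence[i] > 1) {
      add("pathologies", p$pathology[i], "prevalence must lie in [0, 1]")
    }
    dx <- c(p$dx_mild[i], p$dx_moderate[i], p$dx_severe[i])
    if (any(dx < 0 | dx > 1)) {
      add("pathologies", p$pathology[i],
          "diagnosed fractions must lie in [0, 1]")
    }
  }

  e <- bundle$elicitation
  for (q in unique(e$question_id)) {
    eq <- e[e$question_id == q, ]
    ok <- tryCatch({ validate_panel(eq); TRUE },
                   error = function(err) conditionMessage(err))
    if (!isTRUE(ok)) add("elicitation", q, ok)
  }

  b <- bundle$cost_baskets
  for (i in seq_len(nrow(b))) {
    where <- sprintf("%s/%s/%s", b$pathology[i], b$state[i], b$resource[i])
    if (is.na(b$unit_price_clp[i]) || b$unit_price_clp[i] < 0) {
      add("cost_baskets", where, "unit_price_clp must be >= 0")
    }
    if (is.na(b$monthly_quantity[i]) || b$monthly_quantity[i] < 0) {
      add("cost_baskets", where, "monthly_quantity must be >= 0")
    }
    if (is.na(b$user_fraction[i]) || b$user_fraction[i] < 0 ||
        b$user_fraction[i] > 1) {
      add("cost_baskets", where, "user_fraction must lie in [0, 1]")
    }
    if (!b$category[i] %in% COST_CATEGORIES) {
      add("cost_baskets", where,
          sprintf("unknown category '%s'", b$category[i]))
    }
  }

  bu <- bundle$burden
  for (i in seq_len(nrow(bu))) {
    w <- bu$pathology[i]
    if (bu$disability_weight[i] < 0 || bu$disability_weight[i] > 1) {
      add("burden", w, "disability_weight must lie in [0, 1]")
    }
    if (bu$pain_domain_fraction[i] < 0 || bu$pain_domain_fraction[i] > 1) {
      add("burden", w, "pain_domain_fraction must lie in [0, 1]")
    }
    if (bu$duration_years[i] <= 0) add("burden", w, "duration_years must be > 0")
    if (bu$depression_relative_risk[i] < 0) {
      add("burden", w, "depression_relative_risk must be >= 0")
    }
    for (cl in c("depression_exposure_prevalence", "anxiety_proportion")) {
      if (bu[[cl]][i] < 0 || bu[[cl]][i] > 1) {
        add("burden", w, sprintf("%s must lie in [0, 1]", cl))
      }
    }
  }

  pr <- bundle$productivity
  for (i in seq_len(nrow(pr))) {
    w <- pr$pathology[i]
    if (!isTRUE(pr$structural_zero[i])) {
      for (cl in c("leave_episodes", "mean_days_per_episode", "daily_wage_usd")) {
        if (is.na(pr[[cl]][i]) || pr[[cl]][i] < 0) {
          add("productivity", w, sprintf("%s must be >= 0", cl))
        }
      }
      if (pr$system_paid_fraction[i] < 0 || pr$system_paid_fraction[i] > 1) {
        add("productivity", w, "system_paid_fraction must lie in [0, 1]")
      }
    }
  }

  if (length(v) == 0L) {
    tibble::tibble(component = character(), where = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

# model assembly -----------------------------------------------------------

# Static (non-resampled) structure shared by all evaluations of one
# bundle + scenario: diagnosed fractions, cost multipliers, leave rates,
# background depression cases, currency, horizon.
prepare_model <- function(bundle, scenario) {
  p <- bundle$pathologies
  paths <- p$pathology
  dx <- if (scenario$scenario == "undiagnosed") {
    u <- scenario$undiagnosed_fractions
    c(1 - u[["mild"]], 1 - u[["moderate"]], 1)
  } else {
    c(1, 1, 1)
  }
  cost_mult <- matrix(1, nrow = length(paths), ncol = 3L,
                      dimnames = list(paths, LIVING_STATES))
  mfs_split_override <- NULL
  if ("mfs" %in% paths) {
    cf <- unname(scenario$consult_fractions)
    if (scenario$mfs_split_mode == "normalized_consult") {
      mfs_split_override <- cf / sum(cf)
    } else {
      cost_mult["mfs", ] <- cf
    }
  }
  pr <- bundle$productivity
  leave_rate <- ifelse(pr$structural_zero, NA_real_,
                       pr$leave_episodes / pmax(p$prevalent_count, 1))
  population <- bundle$manifest$config$population_size
  if (is.null(population)) {
    population <- sum(p$prevalent_count) / max(sum(p$prevalence), 1e-12)
  }
  list(
    paths = paths,
    population = as.numeric(population),
    dx = dx,
    mfs_split_override = mfs_split_override,
    cost_mult = cost_mult,
    horizon = scenario$horizon_cycles,
    clp_per_usd = scenario$currency$clp_per_usd,
    duration_years = bundle$burden$duration_years,
    background_dep_cases = bundle$burden$depression_background_cases,
    leave_rate = leave_rate,
    daily_wage = pr$daily_wage_usd,
    structural_zero = pr$structural_zero
  )
}

# Flat parameter list at bundle base values; the PSA distribution map and
# one-way SA vary entries of this list.
base_parameters <- function(bundle, scenario) {
  p <- bundle$pathologies
  bu <- bundle$burden
  pr <- bundle$productivity
  pooled <- pooled_densities(bundle)
  params <- list(
    monthly_death = mortality_parameter(
      bundle$settings$annual_mortality_per_1000)$monthly_probability
  )
  for (lab in transition_labels()) {
    params[[paste0("t_", lab)]] <- elicited_mean(pooled[[lab]])
  }
  costs <- state_cost_table(bundle$cost_baskets,
                            fx = scenario$currency)
  for (i in seq_len(nrow(p))) {
    pp <- p$pathology[i]
    params[[paste0("prev_", pp)]] <- p$prevalence[i]
    params[[paste0("split_", pp)]] <- c(p$split_mild[i], p$split_moderate[i],
                                        p$split_severe[i])
    for (st in LIVING_STATES) {
      cc <- costs$monthly_cost_clp[costs$pathology == pp & costs$state == st]
      params[[paste0("cost_", pp, "_", st)]] <- cc
    }
    params[[paste0("dw_", pp)]] <- bu$disability_weight[i]
    params[[paste0("pain_", pp)]] <- bu$pain_domain_fraction[i]
    params[[paste0("rr_", pp)]] <- bu$depression_relative_risk[i]
    params[[paste0("anxp_", pp)]] <- bu$anxiety_proportion[i]
    params[[paste0("depcost_", pp)]] <- bu$depression_cost_per_case_usd[i]
    params[[paste0("anxcost_", pp)]] <- bu$anxiety_cost_per_case_usd[i]
    params[[paste0("days_", pp)]] <- if (pr$structural_zero[i]) 0 else
      pr$mean_days_per_episode[i]
    params[[paste0("paid_", pp)]] <- pr$system_paid_fraction[i]
  }
  params
}

#' Pool the elicitation panels of a bundle
#'
#' @param bundle A `pain_bundle`.
#' @return Named list of `pooled_density` objects, one per transition
#'   question.
#' @export
pooled_densities <- function(bundle) {
  stopifnot(inherits(bundle, "pain_bundle"))
  qs <- unique(bundle$elicitation$question_id)
  out <- lapply(qs, function(q) {
    pool_judgements(bundle$elicitation[bundle$elicitation$question_id == q, ])
  })
  setNames(out, qs)
}

# The full-model evaluator: params -> named outcome vector. `detail = TRUE`
# additionally returns traces and per-pathology tables for reporting.
evaluate_params <- function(params, static, detail = FALSE) {
  elicited <- setNames(
    lapply(transition_labels(), function(l) params[[paste0("t_", l)]]),
    transition_labels())
  tm <- build_transition_matrix(elicited, params$monthly_death)
  m <- unclass(tm)
  h <- static$horizon
  n_path <- length(static$paths)
  per <- vector("list", n_path)
  traces <- vector("list", n_path)
  for (i in seq_len(n_path)) {
    pp <- static$paths[i]
    prevalence <- params[[paste0("prev_", pp)]]
    prevalent <- prevalence * static$population
    split <- params[[paste0("split_", pp)]]
    split <- split / sum(split)
    if (pp == "mfs" && !is.null(static$mfs_split_override)) {
      split <- static$mfs_split_override
    }
    init <- c(prevalent * split * static$dx, 0)
    occ <- matrix(0, h + 1L, 4L, dimnames = list(NULL, STATES))
    occ[1L, ] <- init
    for (t in seq_len(h)) occ[t + 1L, ] <- occ[t, ] %*% m
    pm <- colSums(occ[seq_len(h), 1:3, drop = FALSE])
    state_costs <- vapply(LIVING_STATES, function(st)
      params[[paste0("cost_", pp, "_", st)]], numeric(1L))
    direct_clp <- sum(pm * state_costs * static$cost_mult[pp, ])
    diagnosed <- prevalent * sum(split * static$dx)
    ylds <- yld(diagnosed, static$duration_years[i],
                params[[paste0("dw_", pp)]], params[[paste0("pain_", pp)]])
    # PSA draws can push the relative risk slightly below 1; a negative
    # attributable fraction carries no attributable depression cases
    paf_i <- max(0, paf(prevalence, params[[paste0("rr_", pp)]]))
    gate_shares <- if (diagnosed > 0) {
      setNames(split * static$dx / sum(split * static$dx), LIVING_STATES)
    } else {
      setNames(c(0, 0, 0), LIVING_STATES)
    }
    dep_cases <- attributable_depression(paf_i, static$background_dep_cases[i],
                                         gate_shares)
    dep_cost <- dep_cases * params[[paste0("depcost_", pp)]]
    anx_cases <- params[[paste0("anxp_", pp)]] * prevalent
    anx_cost <- anx_cases * params[[paste0("anxcost_", pp)]]
    if (static$structural_zero[i]) {
      societal <- NA_real_; prod_cost <- NA_real_
    } else {
      episodes <- static$leave_rate[i] * prevalent
      societal <- episodes * params[[paste0("days_", pp)]] *
        static$daily_wage[i]
      prod_cost <- societal * params[[paste0("paid_", pp)]]
    }
    per[[i]] <- c(direct_clp = direct_clp, ylds = ylds,
                  dep_cases = dep_cases, dep_cost = dep_cost,
                  anx_cases = anx_cases, anx_cost = anx_cost,
                  societal = societal, prod_cost = prod_cost,
                  prevalent = prevalent, diagnosed = diagnosed)
    if (detail) {
      tr <- tibble::tibble(
        cycle = rep(0:h, times = 4L),
        state = factor(rep(STATES, each = h + 1L), levels = STATES),
        occupancy = as.numeric(occ))
      class(tr) <- c("cohort_trace", class(tr))
      attr(tr, "cycle_length_months") <- 1L
      attr(tr, "horizon_cycles") <- h
      traces[[i]] <- tr
    }
  }
  tab <- do.call(rbind, per)
  rate <- static$clp_per_usd
  direct_usd <- tab[, "direct_clp"] / rate
  dep_cost <- tab[, "dep_cost"]
  anx_cost <- tab[, "anx_cost"]
  prod_cost <- ifelse(is.na(tab[, "prod_cost"]), 0, tab[, "prod_cost"])
  total_usd <- direct_usd + dep_cost + anx_cost + prod_cost
  out <- c(
    total_cost_usd_mm = sum(total_usd) / 1e6,
    direct_cost_usd_mm = sum(direct_usd) / 1e6,
    depression_cost_usd_mm = sum(dep_cost) / 1e6,
    anxiety_cost_usd_mm = sum(anx_cost) / 1e6,
    productivity_cost_usd_mm = sum(prod_cost) / 1e6,
    total_ylds = sum(tab[, "ylds"]),
    depression_cases = sum(tab[, "dep_cases"]),
    setNames(total_usd / 1e6, paste0("cost_", static$paths, "_usd_mm"))
  )
  if (!detail) return(out)
  per_tab <- tibble::as_tibble(tab) |>
    dplyr::mutate(pathology = static$paths, .before = 1L) |>
    dplyr::mutate(
      direct_usd = .data$direct_clp / rate,
      total_usd = total_usd,
      total_clp = total_usd * rate
    )
  list(outcomes = out, per_pathology = per_tab,
       traces = setNames(traces, static$paths))
}

#' Deterministic model evaluation
#'
#' Runs the full cost-consequence pipeline at the bundle's base parameter
#' values (elicited transition means, basket costs, burden inputs) under a
#' scenario, returning the outcome totals plus per-pathology detail and the
#' cohort traces.
#'
#' @param bundle A `pain_bundle` (or bundle directory path).
#' @param scenario A [scenario_config()].
#' @return List with `outcomes` (named vector), `per_pathology` (tibble),
#'   `traces` (named list of `cohort_trace`).
#' @export
evaluate_model <- function(bundle, scenario = scenario_config()) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  static <- prepare_model(bundle, scenario)
  params <- base_parameters(bundle, scenario)
  evaluate_params(params, static, detail = TRUE)
}

#' Default PSA distribution map for a bundle
#'
#' Assigns the standard second-order uncertainty distributions: pooled
#' empirical densities for the six elicited transitions, Dirichlet for
#' severity splits (moment-matched to the bundle split at the given
#' concentration), beta for proportions and probabilities, gamma for the
#' state-level monthly basket costs and per-case costs. Mortality is held
#' fixed by default.
#'
#' @param bundle A `pain_bundle`.
#' @param scenario A [scenario_config()].
#' @param split_concentration Dirichlet concentration for severity splits
#'   (default 60).
#' @param cost_cv Coefficient of variation for gamma cost distributions
#'   (default 0.2).
#' @param proportion_concentration Beta concentration for proportions
#'   (default 100).
#' @return Named list of `param_dist` specs covering [base_parameters()].
#' @export
default_distribution_map <- function(bundle, scenario = scenario_config(),
                                     split_concentration = 60,
                                     cost_cv = 0.2,
                                     proportion_concentration = 100) {
  params <- base_parameters(bundle, scenario)
  pooled <- pooled_densities(bundle)
  dm <- list(monthly_death = dist_fixed(params$monthly_death))
  for (lab in transition_labels()) {
    dm[[paste0("t_", lab)]] <- dist_empirical(pooled[[lab]])
  }
  beta_or_fixed <- function(v, conc) {
    if (v <= 0 || v >= 1) dist_fixed(v) else dist_beta(v, conc)
  }
  gamma_or_fixed <- function(v, cv) {
    if (v <= 0) dist_fixed(v) else dist_gamma(v, cv)
  }
  for (pp in bundle$pathologies$pathology) {
    dm[[paste0("prev_", pp)]] <- beta_or_fixed(params[[paste0("prev_", pp)]],
                                               proportion_concentration)
    dm[[paste0("split_", pp)]] <- dist_dirichlet(
      params[[paste0("split_", pp)]] * split_concentration)
    for (st in LIVING_STATES) {
      nm <- paste0("cost_", pp, "_", st)
      dm[[nm]] <- gamma_or_fixed(params[[nm]], cost_cv)
    }
    dm[[paste0("dw_", pp)]] <- beta_or_fixed(params[[paste0("dw_", pp)]],
                                             proportion_concentration)
    dm[[paste0("pain_", pp)]] <- beta_or_fixed(params[[paste0("pain_", pp)]],
                                               proportion_concentration)
    rr <- params[[paste0("rr_", pp)]]
    dm[[paste0("rr_", pp)]] <- if (rr == 1) dist_fixed(1) else
      gamma_or_fixed(rr, 0.15)
    dm[[paste0("anxp_", pp)]] <- beta_or_fixed(params[[paste0("anxp_", pp)]],
                                               proportion_concentration)
    dm[[paste0("depcost_", pp)]] <- gamma_or_fixed(
      params[[paste0("depcost_", pp)]], cost_cv)
    dm[[paste0("anxcost_", pp)]] <- gamma_or_fixed(
      params[[paste0("anxcost_", pp)]], cost_cv)
    dm[[paste0("days_", pp)]] <- gamma_or_fixed(params[[paste0("days_", pp)]],
                                                cost_cv)
    dm[[paste0("paid_", pp)]] <- beta_or_fixed(params[[paste0("paid_", pp)]],
                                               proportion_concentration)
  }
  dm
}

#' Run the PSA over a bundle
#'
#' Convenience wrapper: builds the model evaluator and the default
#' distribution map for a bundle + scenario and calls [run_psa()].
#'
#' @param bundle A `pain_bundle` (or bundle directory path).
#' @param scenario A [scenario_config()]; `scenario$psa` supplies the
#'   iteration count, level and seed.
#' @param distribution_map Optional override of
#'   [default_distribution_map()].
#' @return A `psa_result`.
#' @export
run_bundle_psa <- function(bundle, scenario = scenario_config(),
                           distribution_map = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  static <- prepare_model(bundle, scenario)
  if (is.null(distribution_map)) {
    distribution_map <- default_distribution_map(bundle, scenario)
  }
  cfg <- psa_config(
    n_iterations = scenario$psa$n_iterations,
    credibility_level = scenario$psa$credibility_level,
    seed = scenario$psa$seed,
    distribution_map = distribution_map
  )
  run_psa(function(p) evaluate_params(p, static), cfg)
}

# report writing -----------------------------------------------------------

config_hash <- function(obj) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full pipeline and write a report bundle
#'
#' Validates the input bundle, runs the deterministic model under the base
#' case and the reduced-diagnosis scenario, runs the PSA under the
#' requested scenario, and writes tidy CSV reports plus a run manifest
#' (seed, config hash, package version — no timestamps, so a rerun with
#' identical inputs is byte-identical).
#'
#' Files written: `trace.csv` (pathology, cycle, state, occupancy),
#' `costs.csv` and `consequences.csv` (per pathology, CLP and USD),
#' `cost_breakdown.csv` (category shares), `scenario_comparison.csv`
#' (base vs reduced-diagnosis totals and percent decrease),
#' `psa_summary.csv`, `psa_samples.csv`, `tornado.csv`, `summary.json`
#' and `manifest.json`.
#'
#' @param bundle A `pain_bundle` or bundle directory path.
#' @param scenario A [scenario_config()].
#' @param output_dir Directory for the report (created if missing).
#' @param psa Run the probabilistic sensitivity analysis (default TRUE).
#' @return Invisibly, a list with the deterministic results of both
#'   scenarios, the `psa_result` (if run), the tornado table, and
#'   `output_dir`.
#' @export
run_pipeline <- function(bundle, scenario = scenario_config(),
                         output_dir, psa = TRUE) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  violations <- validate_bundle(bundle)
  if (nrow(violations) > 0L) {
    msgs <- sprintf("%s [%s]: %s", violations$component, violations$where,
                    violations$message)
    abort(paste0("Bundle failed validation (", nrow(violations),
                 " violations):\n", paste(head(msgs, 20L), collapse = "\n")))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- scenario$currency

  base_sc <- scenario; base_sc$scenario <- "base"
  undx_sc <- scenario; undx_sc$scenario <- "undiagnosed"
  det_base <- evaluate_model(bundle, base_sc)
  det_undx <- evaluate_model(bundle, undx_sc)
  det <- if (scenario$scenario == "base") det_base else det_undx

  trace_tbl <- purrr::imap_dfr(det$traces, function(tr, p) {
    dplyr::mutate(tibble::as_tibble(tr), pathology = p, .before = 1L)
  })
  readr::write_csv(trace_tbl, file.path(output_dir, "trace.csv"))

  costs_tbl <- det$per_pathology |>
    dplyr::transmute(
      pathology = .data$pathology,
      direct_cost_clp = .data$direct_clp,
      direct_cost_usd = .data$direct_usd,
      total_cost_clp = .data$total_clp,
      total_cost_usd = .data$total_usd
    )
  readr::write_csv(costs_tbl, file.path(output_dir, "costs.csv"))

  static <- prepare_model(bundle, scenario)
  baskets <- bundle$cost_baskets
  if (scenario$mfs_split_mode == "multiplier" && "mfs" %in% static$paths) {
    mult <- static$cost_mult["mfs", ]
    sel <- baskets$pathology == "mfs"
    baskets$user_fraction[sel] <- baskets$user_fraction[sel] *
      mult[baskets$state[sel]]
  }
  breakdown <- cost_breakdown(baskets, det$traces) |>
    dplyr::mutate(cost_usd = to_usd(.data$cost_clp, fx))
  readr::write_csv(breakdown, file.path(output_dir, "cost_breakdown.csv"))

  consequences <- det$per_pathology |>
    dplyr::transmute(
      pathology = .data$pathology,
      prevalent_cases = .data$prevalent,
      modelled_cases = .data$diagnosed,
      ylds = .data$ylds,
      depression_cases = .data$dep_cases,
      depression_cost_usd = .data$dep_cost,
      anxiety_cases = .data$anx_cases,
      anxiety_cost_usd = .data$anx_cost,
      productivity_societal_usd = .data$societal,
      productivity_system_cost_usd = .data$prod_cost,
      productivity_structural_zero = static$structural_zero,
      productivity_note = ifelse(static$structural_zero,
                                 "not estimable (no ICD-10 code)", "")
    )
  readr::write_csv(consequences, file.path(output_dir, "consequences.csv"))

  base_total <- det_base$outcomes[["total_cost_usd_mm"]]
  undx_total <- det_undx$outcomes[["total_cost_usd_mm"]]
  comparison <- tibble::tibble(
    scenario = c("base", "undiagnosed"),
    total_cost_usd_mm = c(base_total, undx_total),
    total_cost_clp_mm = c(base_total, undx_total) * fx$clp_per_usd,
    percent_decrease_vs_base = c(0, percent_decrease(base_total, undx_total))
  )
  readr::write_csv(comparison, file.path(output_dir, "scenario_comparison.csv"))

  psa_res <- NULL
  if (isTRUE(psa)) {
    psa_res <- run_bundle_psa(bundle, scenario)
    psum <- psa_res$summary |>
      dplyr::mutate(dplyr::across(
        c("point", "mean", "bci_low", "bci_high"),
        ~ ifelse(grepl("usd", .data$outcome),
                 .x * fx$clp_per_usd, NA_real_),
        .names = "{.col}_clp_scale"))
    readr::write_csv(psum, file.path(output_dir, "psa_summary.csv"))
    readr::write_csv(psa_res$samples, file.path(output_dir, "psa_samples.csv"))
  }

  params <- base_parameters(bundle, scenario)
  key_params <- c("monthly_death", paste0("t_", transition_labels()),
                  paste0("cost_", static$paths[1L], "_", LIVING_STATES))
  ranges <- tibble::tibble(
    parameter = key_params,
    low = vapply(key_params, function(k) {
      v <- params[[k]]; max(0, v * 0.8)
    }, numeric(1L)),
    high = vapply(key_params, function(k) {
      v <- params[[k]]
      if (grepl("^(t_|monthly_death)", k)) min(1, v * 1.2) else v * 1.2
    }, numeric(1L))
  )
  tornado <- tornado_table(function(p) evaluate_params(p, static),
                           params, ranges, outcome = "total_cost_usd_mm")
  readr::write_csv(tornado, file.path(output_dir, "tornado.csv"))

  summary <- list(
    scenario = scenario$scenario,
    total_cost_usd_mm = det$outcomes[["total_cost_usd_mm"]],
    total_cost_clp_mm = det$outcomes[["total_cost_usd_mm"]] * fx$clp_per_usd,
    total_ylds = det$outcomes[["total_ylds"]],
    depression_cost_usd_mm = det$outcomes[["depression_cost_usd_mm"]],
    anxiety_cost_usd_mm = det$outcomes[["anxiety_cost_usd_mm"]],
    productivity_cost_usd_mm = det$outcomes[["productivity_cost_usd_mm"]],
    undiagnosed_percent_decrease = percent_decrease(base_total, undx_total)
  )
  if (!is.null(scenario$gdp_denominator_usd)) {
    summary$cost_gdp_share_percent <-
      det$outcomes[["total_cost_usd_mm"]] * 1e6 /
      scenario$gdp_denominator_usd * 100
  }
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    schema_version = bundle$manifest$schema_version,
    bundle_seed = bundle$manifest$seed,
    psa_seed = scenario$psa$seed,
    config_hash = config_hash(list(scenario = unclass(scenario),
                                   bundle_manifest = bundle$manifest)),
    package_version = as.character(utils::packageVersion("paincohort"))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(base = det_base, undiagnosed = det_undx, psa = psa_res,
                 tornado = tornado, output_dir = output_dir))
}
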