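# Synthetic parameter-set generator: a complete, internally consistent
# stand-in for the study's input table, with known ground truth, so every
# downstream stage (elicitation pooling, cohort trace, costing, burden,
# PSA) is testable without external data.

DEFAULT_PATHOLOGIES <- c("knee_oa", "hip_oa", "lbp", "csp", "mfs", "fm")

# Monthly off-diagonal transition probabilities used as elicitation ground
# truth: chronic pain under usual management is persistent, with modest
# monthly improvement/worsening flows.
DEFAULT_TRUE_TRANSITIONS <- c(
  mild_to_moderate = 0.15, mild_to_severe = 0.03,
  moderate_to_mild = 0.12, moderate_to_severe = 0.10,
  severe_to_mild = 0.03, severe_to_moderate = 0.12
)

# Synthetic disability-weight means per pathology (magnitudes in the range
# reported for musculoskeletal conditions in burden-of-disease studies).
DEFAULT_DW_MEANS <- c(
  knee_oa = 0.13, hip_oa = 0.13, lbp = 0.21, csp = 0.11, mfs = 0.10, fm = 0.12
)

#' Configuration for the synthetic parameter-set generator
#'
#' Defines the study conditions emulated by [generate_parameter_set()]:
#' six musculoskeletal pathologies, an adult population, per-pathology
#' prevalence and mild/moderate/severe severity splits, a 13-expert,
#' 21-bin elicitation panel per transition question, and gamma/beta
#' distributed cost and proportion parameters.
#'
#' @param n_pathologies Number of pathologies (default 6).
#' @param pathology_names Labels, length `n_pathologies`.
#' @param population_size Adult population at risk (default 13,000,000).
#' @param prevalence_range Interval in \[0, 1\] that per-pathology prevalence
#'   is drawn from (default `c(0.01, 0.11)`).
#' @param severity_split_concentration Dirichlet concentration controlling
#'   the spread of severity splits around the base split (default 60).
#' @param true_transition_probs Named vector of ground-truth monthly
#'   off-diagonal transition probabilities.
#' @param n_experts Panel size per question (default 13).
#' @param n_bins Number of grid options per question (default 21).
#' @param expert_concentration Beta concentration controlling how tightly
#'   experts cluster around the truth (default 40).
#' @param cost_scale Multiplier on the reference basket unit prices
#'   (default 1).
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the config including the seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_pathologies = 6L,
                         pathology_names = DEFAULT_PATHOLOGIES,
                         population_size = 13e6,
                         prevalence_range = c(0.01, 0.11),
                         severity_split_concentration = 60,
                         true_transition_probs = DEFAULT_TRUE_TRANSITIONS,
                         n_experts = 13L,
                         n_bins = 21L,
                         expert_concentration = 40,
                         cost_scale = 1,
                         seed = 1L) {
  n_pathologies <- check_count(n_pathologies, "n_pathologies", min = 1L)
  if (length(pathology_names) != n_pathologies ||
      anyDuplicated(pathology_names)) {
    abort("`pathology_names` must be n_pathologies distinct labels.")
  }
  check_count(population_size, "population_size", min = 1L)
  check_probability(prevalence_range, "prevalence_range", allow_vector = TRUE)
  if (length(prevalence_range) != 2L ||
      prevalence_range[1] > prevalence_range[2]) {
    abort("`prevalence_range` must be an ordered interval within [0, 1].")
  }
  check_positive(severity_split_concentration, "severity_split_concentration")
  missing <- setdiff(transition_labels(), names(true_transition_probs))
  if (length(missing) > 0L) {
    abort(paste0("`true_transition_probs` is missing: ",
                 paste(missing, collapse = ", ")))
  }
  check_probability(unname(true_transition_probs), "true_transition_probs",
                    allow_vector = TRUE)
  check_count(n_experts, "n_experts", min = 1L)
  check_count(n_bins, "n_bins", min = 2L)
  check_positive(expert_concentration, "expert_concentration")
  check_positive(cost_scale, "cost_scale")
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      n_pathologies = n_pathologies,
      pathology_names = as.character(pathology_names),
      population_size = as.numeric(population_size),
      prevalence_range = as.numeric(prevalence_range),
      severity_split_concentration = severity_split_concentration,
      true_transition_probs = true_transition_probs[transition_labels()],
      n_experts = as.integer(n_experts),
      n_bins = as.integer(n_bins),
      expert_concentration = expert_concentration,
      cost_scale = cost_scale,
      seed = seed
    ),
    class = "synth_config"
  )
}

# moment-matched samplers -------------------------------------------------

rbeta_mc <- function(n, mean, concentration) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  rbeta(n, mean * concentration, (1 - mean) * concentration)
}

rgamma_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

# bin grid: midpoints of an even partition of [0, 1]
bin_grid <- function(n_bins) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  list(edges = edges, mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2)
}

#' Generate a synthetic expert elicitation panel
#'
#' Simulates a panel of experts each encoding their belief about one
#' transition probability as a normalized histogram over a shared grid of
#' `n_bins` candidate values (the midpoints of an even partition of
#' \[0, 1\]). Each expert's central belief is drawn from a Beta distribution
#' moment-matched to (`true_p`, `concentration`) — so the expert-level
#' expectation is `true_p` — and the histogram is the discretization of a
#' Beta with that mean and the same concentration. With
#' `concentration = Inf` every expert puts mass 1 on the bin containing
#' `true_p`.
#'
#' @param true_p Ground-truth probability in \[0, 1\].
#' @param n_experts Panel size (default 13).
#' @param n_bins Grid size (default 21).
#' @param concentration Beta concentration (> 0, or `Inf` for the
#'   degenerate limit).
#' @param seed Optional integer seed; if `NULL`, the current RNG state is
#'   used (so panels embedded in a larger seeded generation stay
#'   reproducible).
#' @return Long tibble: `expert_id`, `bin_midpoint`, `weight`; each
#'   expert's weights sum to 1.
#' @examples
#' panel <- generate_expert_panel(0.3, seed = 42)
#' dplyr::count(panel, expert_id, wt = weight)
#' @export
generate_expert_panel <- function(true_p, n_experts = 13L, n_bins = 21L,
                                  concentration = 40, seed = NULL) {
  check_probability(true_p, "true_p")
  n_experts <- check_count(n_experts, "n_experts", min = 1L)
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0) {
    abort("`concentration` must be positive (possibly Inf).")
  }
  if (!is.null(seed)) set.seed(seed)
  g <- bin_grid(n_bins)
  ids <- sprintf("expert_%02d", seq_len(n_experts))
  rows <- lapply(seq_len(n_experts), function(i) {
    if (is.infinite(concentration) || true_p <= 0 || true_p >= 1) {
      w <- numeric(n_bins)
      w[which.min(abs(g$mid - true_p))] <- 1
    } else {
      m <- rbeta_mc(1L, true_p, concentration)
      if (m <= 0 || m >= 1) {
        w <- numeric(n_bins)
        w[which.min(abs(g$mid - m))] <- 1
      } else {
        a <- m * concentration
        b <- (1 - m) * concentration
        w <- diff(pbeta(g$edges, a, b))
        w <- w / sum(w)
      }
    }
    tibble::tibble(expert_id = ids[i], bin_midpoint = g$mid, weight = w)
  })
  dplyr::bind_rows(rows)
}

#' Generate a complete synthetic model input bundle
#'
#' Produces everything the downstream pipeline needs, as a deterministic
#' function of the config: per-pathology prevalent cohorts with severity
#' splits, one elicitation panel per living-state transition question,
#' per-pathology per-state cost baskets (unit prices gamma-jittered around
#' the packaged reference baskets), burden-of-disease inputs (disability
#' weights, pain-domain fractions, depression/anxiety attribution inputs),
#' productivity-loss inputs (with a structural zero for myofascial
#' syndrome, which is not identifiable in medical-leave records), and
#' scenario settings.
#'
#' @param config A [synth_config()].
#' @return A `pain_bundle` list with elements `pathologies`, `elicitation`,
#'   `cost_baskets`, `burden`, `productivity`, `settings`, `manifest`.
#' @examples
#' bundle <- generate_parameter_set(synth_config(seed = 1))
#' bundle$pathologies
#' @export
generate_parameter_set <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be created with synth_config().")
  }
  set.seed(config$seed)
  paths <- config$pathology_names
  n <- config$n_pathologies

  # prevalent cohorts and severity splits
  lo <- config$prevalence_range[1]; hi <- config$prevalence_range[2]
  prevalence <- lo + (hi - lo) * rbeta(n, 2, 2)
  base_split <- c(0.30, 0.45, 0.25)
  alpha <- base_split * config$severity_split_concentration
  splits <- t(vapply(seq_len(n), function(i) {
    x <- rgamma(3L, shape = alpha, scale = 1)
    x / sum(x)
  }, numeric(3L)))
  pathologies <- tibble::tibble(
    pathology = paths,
    prevalence = prevalence,
    prevalent_count = round(prevalence * config$population_size),
    split_mild = splits[, 1], split_moderate = splits[, 2],
    split_severe = splits[, 3],
    dx_mild = 1, dx_moderate = 1, dx_severe = 1
  )

  # elicitation panels: one per off-diagonal transition question
  elicitation <- dplyr::bind_rows(lapply(transition_labels(), function(lab) {
    panel <- generate_expert_panel(
      true_p = config$true_transition_probs[[lab]],
      n_experts = config$n_experts, n_bins = config$n_bins,
      concentration = config$expert_concentration
    )
    dplyr::mutate(panel, question_id = lab, .before = 1L)
  }))

  # cost baskets: reference baskets with gamma-jittered unit prices
  ref <- reference_baskets()
  cost_baskets <- dplyr::bind_rows(lapply(paths, function(p) {
    b <- ref
    b$unit_price_clp <- rgamma_cv(nrow(b), 1, 0.15) * b$unit_price_clp *
      config$cost_scale
    dplyr::mutate(b, pathology = p, .before = 1L)
  }))

  # burden-of-disease inputs (synthetic defaults; depression relative risk
  # fixed at 1 for knee/hip OA so their attributable fraction is zero)
  dw_mean <- unname(DEFAULT_DW_MEANS[match(paths, names(DEFAULT_DW_MEANS))])
  dw_mean[is.na(dw_mean)] <- 0.12
  rr <- rgamma_cv(n, 2, 0.15)
  rr[paths %in% c("knee_oa", "hip_oa")] <- 1
  burden <- tibble::tibble(
    pathology = paths,
    case_basis = "prevalent",
    duration_years = 1,
    disability_weight = vapply(dw_mean, function(m) rbeta_mc(1L, m, 100),
                               numeric(1L)),
    pain_domain_fraction = rbeta_mc(n, 0.7, 50),
    depression_exposure_prevalence = prevalence,
    depression_relative_risk = rr,
    depression_background_cases = round(0.176 * config$population_size),
    anxiety_proportion = rbeta_mc(n, 0.06, 150),
    depression_cost_per_case_usd = rgamma_cv(n, 400, 0.2),
    anxiety_cost_per_case_usd = rgamma_cv(n, 250, 0.2)
  )

  # productivity inputs; myofascial syndrome is a structural zero
  productivity <- tibble::tibble(
    pathology = paths,
    leave_episodes = round(pathologies$prevalent_count * rbeta_mc(n, 0.04, 200)),
    mean_days_per_episode = rgamma_cv(n, 12, 0.2),
    daily_wage_usd = rgamma_cv(n, 30, 0.1),
    system_paid_fraction = rbeta_mc(n, 0.7, 100),
    structural_zero = paths == "mfs"
  )
  productivity$leave_episodes[productivity$structural_zero] <- NA_real_
  productivity$mean_days_per_episode[productivity$structural_zero] <- NA_real_

  settings <- list(
    horizon_cycles = 12L,
    annual_mortality_per_1000 = 5.1,
    clp_per_usd = 394.35,
    reference_year = 2015L,
    consult_fractions = c(mild = 0.075, moderate = 0.35, severe = 0.60),
    mfs_split_mode = "normalized_consult",
    undiagnosed_fractions = c(mild = 0.5, moderate = 0.25)
  )
  manifest <- list(
    schema_version = "1.0",
    seed = config$seed,
    config = unclass(config)
  )
  structure(
    list(pathologies = pathologies, elicitation = elicitation,
         cost_baskets = cost_baskets, burden = burden,
         productivity = productivity, settings = settings,
         manifest = manifest),
    class = "pain_bundle"
  )
}

#' Packaged reference cost baskets
#'
#' Synthetic per-state monthly resource baskets calibrated so that the
#' per-patient monthly totals, converted at 394.35 CLP/USD, equal the
#' published reference values USD 63.5 (mild), 101.82 (moderate) and
#' 734.5 (severe); the severe basket carries an emergency-visit item with
#' `user_fraction` 0.9 and a hospitalization item. Line-item composition
#' is the package's own construction.
#'
#' @return Tibble: `state`, `resource`, `category`, `unit_price_clp`,
#'   `monthly_quantity`, `user_fraction`.
#' @export
reference_baskets <- function() {
  path <- system.file("extdata", "synthetic_reference_baskets.csv",
                      package = "paincohort", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    state = readr::col_character(),
                    resource = readr::col_character(),
                    category = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

# bundle serialization ----------------------------------------------------

#' Write a model input bundle to a directory
#'
#' Serializes the bundle as CSV tables plus one JSON manifest
#' (`manifest.json`, schema versioned, holding the settings and generator
#' config). The round trip through [read_bundle()] is lossless.
#'
#' @param bundle A `pain_bundle`.
#' @param path Directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "pain_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tables <- c("pathologies", "elicitation", "cost_baskets", "burden",
              "productivity")
  for (tb in tables) {
    readr::write_csv(bundle[[tb]], file.path(path, paste0(tb, ".csv")))
  }
  jsonlite::write_json(
    list(schema_version = bundle$manifest$schema_version,
         seed = bundle$manifest$seed,
         config = bundle$manifest$config,
         settings = bundle$settings),
    file.path(path, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a model input bundle from a directory
#'
#' @param path Directory written by [write_bundle()].
#' @return A `pain_bundle`.
#' @export
read_bundle <- function(path) {
  if (!dir.exists(path)) abort(sprintf("Bundle directory not found: %s", path))
  chr_cols <- c("pathology", "question_id", "expert_id", "state", "resource",
                "category", "case_basis")
  # read everything as character, then convert doubles with base R's
  # correctly-rounded strtod so the round trip is exact to the last bit
  read_tb <- function(name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) abort(sprintf("Missing bundle table: %s", f))
    tb <- readr::read_csv(f, show_col_types = FALSE,
                          col_types = readr::cols(
                            .default = readr::col_character()))
    for (cl in names(tb)) {
      if (cl %in% chr_cols) next
      tb[[cl]] <- if (cl == "structural_zero") as.logical(tb[[cl]]) else
        as.numeric(tb[[cl]])
    }
    tb
  }
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  settings <- man$settings
  settings$horizon_cycles <- as.integer(settings$horizon_cycles)
  settings$consult_fractions <- unlist(settings$consult_fractions)
  settings$undiagnosed_fractions <- unlist(settings$undiagnosed_fractions)
  structure(
    list(
      pathologies = read_tb("pathologies"),
      elicitation = read_tb("elicitation"),
      cost_baskets = read_tb("cost_baskets"),
      burden = read_tb("burden"),
      productivity = read_tb("productivity"),
      settings = settings,
      manifest = list(schema_version = man$schema_version, seed = man$seed,
                      config = man$config)
    ),
    class = "pain_bundle"
  )
}

#' @export
print.pain_bundle <- function(x, ...) {
  cat("<pain_bundle>", nrow(x$pathologies), "pathologies;",
      length(unique(x$elicitation$question_id)), "elicited transitions;",
      "seed", x$manifest$seed, "\n")
  invisible(x)
}
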