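test_that("a single expert's point mass pools to a point mass", {
  pooled <- pool_judgements(point_mass_panel(0.3))
  expect_equal(attr(pooled, "n_experts"), 1L)
  nonzero <- pooled[pooled$weight > 0, ]
  expect_equal(nrow(nonzero), 1L)
  expect_equal(sum(pooled$weight), 1, tolerance = 1e-12)
  grid <- seq(1 / 42, 41 / 42, by = 1 / 21)
  expect_equal(elicited_mean(pooled), grid[which.min(abs(grid - 0.3))])
})

test_that("pooling keeps every (expert, bin) option as a support point", {
  panel <- generate_expert_panel(0.4, n_experts = 13, n_bins = 21, seed = 3)
  pooled <- pool_judgements(panel)
  expect_equal(attr(pooled, "n_options"), 273L)
  expect_equal(nrow(pooled), 273L)
  expect_equal(sum(pooled$weight), 1, tolerance = 1e-12)
})

test_that("uniform judgements over a symmetric grid pool to mean 0.5", {
  edges <- seq(0, 1, length.out = 22L)
  mid <- (edges[-1L] + edges[-22L]) / 2
  panel <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(expert_id = paste0("e", i), bin_midpoint = mid,
               weight = rep(1 / 21, 21))
  }))
  expect_equal(elicited_mean(pool_judgements(panel)), 0.5)
})

test_that("elicited mean matches hand arithmetic on a 3-point density", {
  panel <- data.frame(expert_id = "e01",
                      bin_midpoint = c(0.1, 0.5, 0.9),
                      weight = c(0.2, 0.5, 0.3))
  # 0.1*0.2 + 0.5*0.5 + 0.9*0.3 = 0.02 + 0.25 + 0.27 = 0.54
  expect_equal(elicited_mean(pool_judgements(panel)), 0.54)
})

test_that("pooled mean equals the brute-force oracle on random panels", {
  set.seed(99)
  for (i in 1:100) {
    panel <- random_panel(sample(2:15, 1L), sample(5:25, 1L))
    expect_equal(elicited_mean(pool_judgements(panel)),
                 brute_force_pooled_mean(panel), tolerance = 1e-12)
  }
})

test_that("linear pooling is order-invariant in the expert list", {
  panel <- generate_expert_panel(0.3, n_experts = 8, seed = 4)
  shuffled <- panel[order(rev(panel$expert_id), panel$bin_midpoint), ]
  expect_equal(elicited_mean(pool_judgements(panel)),
               elicited_mean(pool_judgements(shuffled)), tolerance = 1e-15)
})

test_that("unequal expert weights shift the pooled mean accordingly", {
  panel <- rbind(point_mass_panel(0.2),
                 transform(point_mass_panel(0.8), expert_id = "e02"))
  pooled <- pool_judgements(panel, expert_weights = c(0.75, 0.25))
  grid <- seq(1 / 42, 41 / 42, by = 1 / 21)
  lo <- grid[which.min(abs(grid - 0.2))]
  hi <- grid[which.min(abs(grid - 0.8))]
  expect_equal(elicited_mean(pooled), 0.75 * lo + 0.25 * hi)
})

test_that("pooling rejects malformed panels", {
  panel <- point_mass_panel(0.3)
  bad <- panel
  bad$weight[1] <- bad$weight[1] + 0.5
  expect_error(pool_judgements(bad), "sum to 1")
  other_grid <- transform(point_mass_panel(0.3, n_bins = 11L),
                          expert_id = "e02")
  expect_error(pool_judgements(rbind(panel, other_grid)), "grid")
  expect_error(pool_judgements(panel[0, ]), "at least one")
  expect_error(pool_judgements(panel, expert_weights = c(0.4, 0.6)),
               "expert_weights")
})

test_that("density sampling reproduces the pooled weights", {
  panel <- rbind(point_mass_panel(0.2),
                 transform(point_mass_panel(0.8), expert_id = "e02"))
  pooled <- pool_judgements(panel)
  set.seed(10)
  draws <- sample_transition_prob(pooled, n = 10000L)
  grid <- seq(1 / 42, 41 / 42, by = 1 / 21)
  lo <- grid[which.min(abs(grid - 0.2))]
  expect_lt(abs(mean(draws == lo) - 0.5), 0.02)
  # point mass always returns its support
  pm <- pool_judgements(point_mass_panel(0.3))
  expect_true(all(sample_transition_prob(pm, 50L) ==
                    pm$support[pm$weight > 0]))
  # same seed, same sequence
  set.seed(11); a <- sample_transition_prob(pooled, 100L)
  set.seed(11); b <- sample_transition_prob(pooled, 100L)
  expect_identical(a, b)
})

test_that("transition matrix assembly rescales living rows by survival", {
  full_rows <- list(
    mild_to_mild = 0.7, mild_to_moderate = 0.2, mild_to_severe = 0.1,
    moderate_to_mild = 0.25, moderate_to_moderate = 0.5,
    moderate_to_severe = 0.25,
    severe_to_mild = 0.1, severe_to_moderate = 0.3, severe_to_severe = 0.6
  )
  m <- build_transition_matrix(full_rows, monthly_death = 0.00042)
  expect_equal(unname(m["mild", ]),
               c(c(0.7, 0.2, 0.1) * (1 - 0.00042), 0.00042),
               tolerance = 1e-12)
  expect_equal(unname(round(m["mild", ], 5)),
               c(0.69971, 0.19992, 0.09996, 0.00042))
  # zero mortality leaves elicited rows untouched
  m0 <- build_transition_matrix(full_rows, monthly_death = 0)
  expect_equal(unname(m0["moderate", ]), c(0.25, 0.5, 0.25, 0))
  expect_equal(unname(m0["dead", ]), c(0, 0, 0, 1))
})

test_that("assembled matrices are always row-stochastic and absorbing", {
  set.seed(21)
  for (i in 1:25) {
    off <- runif(6L, 0, 0.4)
    names(off) <- c("mild_to_moderate", "mild_to_severe", "moderate_to_mild",
                    "moderate_to_severe", "severe_to_mild",
                    "severe_to_moderate")
    m <- build_transition_matrix(as.list(off), monthly_death = runif(1, 0, 0.01))
    expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-9)
    expect_equal(unname(m["dead", ]), c(0, 0, 0, 1))
  }
})

test_that("incoherent rows are renormalized and negatives rejected", {
  rows <- list(
    mild_to_mild = 0.8, mild_to_moderate = 0.3, mild_to_severe = 0.1,
    moderate_to_mild = 0.2, moderate_to_moderate = 0.6,
    moderate_to_severe = 0.2,
    severe_to_mild = 0.1, severe_to_moderate = 0.2, severe_to_severe = 0.7
  )
  m <- build_transition_matrix(rows, monthly_death = 0)
  expect_equal(unname(m["mild", 1:3]), c(0.8, 0.3, 0.1) / 1.2)
  expect_error(
    build_transition_matrix(list(
      mild_to_moderate = 0.6, mild_to_severe = 0.6, moderate_to_mild = 0.1,
      moderate_to_severe = 0.1, severe_to_mild = 0.1,
      severe_to_moderate = 0.1), monthly_death = 0),
    "complement")
  expect_error(
    build_transition_matrix(list(mild_to_moderate = 0.2),
                            monthly_death = 0),
    "Missing elicited transitions")
})

test_that("sampled-mode assembly draws transitions from the densities", {
  b <- small_test_bundle()
  pooled <- pooled_densities(b)
  set.seed(5)
  m1 <- build_transition_matrix(pooled, monthly_death = 0.00042,
                                mode = "sample")
  set.seed(5)
  m2 <- build_transition_matrix(pooled, monthly_death = 0.00042,
                                mode = "sample")
  expect_identical(m1, m2)
  expect_equal(unname(rowSums(m1)), rep(1, 4), tolerance = 1e-9)
  m_mean <- build_transition_matrix(pooled, monthly_death = 0.00042)
  expect_equal(unname(rowSums(m_mean)), rep(1, 4), tolerance = 1e-9)
})
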