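test_that("annual-to-monthly conversion follows the constant-rate formula", {
  expect_equal(annual_to_monthly_prob(0), 0)
  expect_equal(annual_to_monthly_prob(1), 1)
  expect_equal(annual_to_monthly_prob(0.12), 1 - 0.88^(1 / 12),
               tolerance = 1e-15)
  # monotone increasing
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(annual_to_monthly_prob(p)) > 0))
  expect_error(annual_to_monthly_prob(1.2), "\\[0, 1\\]")
  # crude death rates convert through the rate reading: 5.1 per 1000 per
  # year is 0.42 per 1000 per month
  expect_equal(mortality_parameter(5.1)$monthly_probability,
               1 - exp(-0.0051 / 12), tolerance = 1e-15)
  expect_equal(round(mortality_parameter(5.1)$monthly_probability * 1000, 2),
               0.42)
})

test_that("initial allocation splits the diagnosed prevalent cohort", {
  ch <- pathology_cohort("lbp", 1000, c(0.5, 0.3, 0.2))
  expect_equal(initial_state_vector(ch), c(500, 300, 200, 0),
               ignore_attr = TRUE)
  # mirrors the reduced-diagnosis scenario arithmetic
  ch2 <- pathology_cohort("lbp", 1000, c(0.5, 0.3, 0.2),
                          diagnosed_fractions = c(0.5, 0.75, 1.0))
  v <- initial_state_vector(ch2)
  expect_equal(v, c(250, 225, 200, 0), ignore_attr = TRUE)
  expect_equal(unname(attr(v, "undiagnosed")), c(250, 75, 0))
  expect_equal(initial_state_vector(
    pathology_cohort("x", 0, c(0.5, 0.3, 0.2))), c(0, 0, 0, 0),
    ignore_attr = TRUE)
  expect_error(pathology_cohort("x", 10, c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("the trace is constant under the identity matrix", {
  tr <- run_cohort(c(mild = 10, moderate = 5, severe = 2, dead = 0),
                   transition_matrix(diag(4)), 12)
  occ <- matrix(tr$occupancy, ncol = 4)
  expect_true(all(apply(occ, 2, function(col) all(col == col[1]))))
})

test_that("death occupancy matches the matrix-power oracle on a toy", {
  # single living compartment, absorbing death at 0.1 per cycle:
  # dead after 2 cycles = 100 * (1 - 0.9^2) = 19
  m <- transition_matrix(rbind(c(0.9, 0, 0, 0.1), c(0, 0.9, 0, 0.1),
                               c(0, 0, 0.9, 0.1), c(0, 0, 0, 1)))
  tr <- run_cohort(c(mild = 100, moderate = 0, severe = 0, dead = 0), m, 2)
  expect_equal(tr$occupancy[tr$cycle == 2 & tr$state == "dead"], 19)
})

test_that("population is conserved and death is monotone", {
  set.seed(31)
  for (i in 1:50) {
    m <- random_transition_matrix()
    init <- c(runif(3, 0, 1000), 0)
    names(init) <- c("mild", "moderate", "severe", "dead")
    tr <- run_cohort(init, m, 12)
    totals <- tapply(tr$occupancy, tr$cycle, sum)
    expect_true(all(abs(totals - sum(init)) < 1e-6))
    dead <- tr$occupancy[tr$state == "dead"]
    expect_true(all(diff(dead) >= -1e-12))
    expect_true(all(tr$occupancy >= 0))
  }
})

test_that("with zero mortality the living distribution approaches the
           stationary distribution of the living matrix", {
  set.seed(7)
  living <- matrix(runif(9, 0.05, 1), 3, 3)
  living <- living / rowSums(living)
  m <- matrix(0, 4, 4); m[1:3, 1:3] <- living; m[4, 4] <- 1
  tr <- run_cohort(c(mild = 100, moderate = 0, severe = 0, dead = 0),
                   transition_matrix(m), 300)
  final <- tr$occupancy[tr$cycle == 300][1:3] / 100
  # oracle: left eigenvector with eigenvalue 1
  ev <- eigen(t(living))
  i1 <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i1]); stat <- stat / sum(stat)
  expect_equal(final, stat, tolerance = 1e-8)
})

test_that("run_cohort rejects invalid inputs before simulating", {
  bad <- diag(4); bad[1, 1] <- 0.5
  expect_error(run_cohort(c(1, 0, 0, 0), bad, 12), "sum to 1")
  m <- transition_matrix(diag(4))
  expect_error(run_cohort(c(1, 0, 0, -1), m, 12), "non-negative")
  expect_error(run_cohort(c(1, 0, 0, 0), m, 0), "horizon_cycles")
})

test_that("the reduced-diagnosis scenario rewrites diagnosed fractions", {
  cohorts <- list(pathology_cohort("a", 100, c(0.3, 0.4, 0.3)),
                  pathology_cohort("b", 200, c(0.2, 0.5, 0.3)))
  out <- apply_undiagnosed_scenario(cohorts, 0.5, 0.25)
  for (ch in out) {
    expect_equal(unname(ch$diagnosed_fractions), c(0.5, 0.75, 1.0))
  }
  # identity and boundary cases
  same <- apply_undiagnosed_scenario(cohorts, 0, 0)
  expect_equal(unname(same[[1]]$diagnosed_fractions), c(1, 1, 1))
  empty <- apply_undiagnosed_scenario(cohorts, 1, 1)
  v <- initial_state_vector(empty[[1]])
  expect_equal(unname(v[c("mild", "moderate")]), c(0, 0))
  expect_gt(v[["severe"]], 0)
  expect_error(apply_undiagnosed_scenario(cohorts, 1.5, 0), "\\[0, 1\\]")
})

test_that("trace accessors summarize conservation and deaths", {
  m <- transition_matrix(rbind(c(0.9, 0, 0, 0.1), c(0, 0.9, 0, 0.1),
                               c(0, 0, 0.9, 0.1), c(0, 0, 0, 1)))
  tr <- run_cohort(c(mild = 100, moderate = 0, severe = 0, dead = 0), m, 12)
  g <- glance(tr)
  expect_equal(g$initial_cohort, 100)
  expect_equal(g$deaths, 100 * (1 - 0.9^12))
  expect_lt(g$conservation_error, 1e-6)
  expect_s3_class(tidy(tr), "tbl_df")
})
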