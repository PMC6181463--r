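test_that("credibility intervals follow the interpolated-percentile oracle", {
  expect_equal(unname(bci(1:100, 0.95)), c(3.475, 97.525))
  # oracle: direct order-statistic interpolation at h = (n-1)p + 1
  set.seed(12)
  x <- rnorm(257)
  s <- sort(x)
  oracle <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  expect_equal(unname(bci(x, 0.9)), c(oracle(0.05), oracle(0.95)),
               tolerance = 1e-12)
  expect_equal(unname(bci(rep(3.2, 10))), c(3.2, 3.2))
  expect_error(bci(numeric(0)), "non-empty")
  expect_error(bci(1:10, 1.2), "\\(0, 1\\)")
})

test_that("credibility intervals are nested across levels", {
  set.seed(13)
  x <- rgamma(2000, shape = 2, scale = 3)
  levels <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  ints <- t(vapply(levels, function(l) bci(x, l), numeric(2L)))
  expect_true(all(diff(ints[, 1]) <= 1e-12))  # lows decrease
  expect_true(all(diff(ints[, 2]) >= -1e-12)) # highs increase
})

test_that("all-fixed parameters give a degenerate PSA", {
  cfg <- psa_config(n_iterations = 50, seed = 1, distribution_map = list(
    a = dist_fixed(2), b = dist_fixed(3)))
  res <- run_psa(function(p) c(out = p$a * p$b), cfg)
  expect_true(all(res$samples$value == 6))
  expect_equal(res$summary$point, 6)
  expect_equal(res$summary$bci_low, 6)
  expect_equal(res$summary$bci_high, 6)
})

test_that("PSA is deterministic under a fixed seed", {
  cfg <- psa_config(n_iterations = 100, seed = 42, distribution_map = list(
    price = dist_gamma(10, 0.3), frac = dist_beta(0.4, 50)))
  fn <- function(p) c(cost = p$price * p$frac, cases = 100 * p$frac)
  r1 <- run_psa(fn, cfg)
  r2 <- run_psa(fn, cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$summary, r2$summary)
})

test_that("a gamma parameter through a linear pipeline matches closed form", {
  shape <- 4; scale <- 2.5
  cfg <- psa_config(n_iterations = 5000, seed = 7, distribution_map = list(
    price = structure(list(family = "gamma", shape = shape, scale = scale),
                      class = "param_dist")))
  res <- run_psa(function(p) c(cost = 1200 * p$price), cfg)
  samples <- res$samples$value
  closed_form <- 1200 * shape * scale
  mcse <- sd(samples) / sqrt(length(samples))
  expect_lt(abs(mean(samples) - closed_form), 3 * mcse)
  expect_equal(res$summary$point, closed_form)
  # linear map: outcome quantiles equal transformed parameter quantiles
  expect_equal(unname(bci(samples)), unname(1200 * bci(samples / 1200)),
               tolerance = 1e-9)
})

test_that("Monte Carlo error of the mean shrinks as one over sqrt(n)", {
  run_at <- function(n, seed) {
    cfg <- psa_config(n_iterations = n, seed = seed, distribution_map = list(
      price = dist_gamma(10, 0.4), frac = dist_beta(0.3, 30)))
    run_psa(function(p) c(cost = 500 * p$price * p$frac, dummy = p$price), cfg)
  }
  ns <- c(500, 2000, 5000)
  ses <- vapply(seq_along(ns), function(i) {
    s <- run_at(ns[i], seed = 100 + i)$samples
    v <- s$value[s$outcome == "cost"]
    sd(v) / sqrt(length(v))
  }, numeric(1L))
  expect_true(all(diff(ses) < 0))
  ratio <- ses[1] / ses[3]
  expect_gt(ratio, sqrt(10) * 0.75)
  expect_lt(ratio, sqrt(10) * 1.33)
})

test_that("dirichlet and empirical families are sampled coherently", {
  panel <- generate_expert_panel(0.3, n_experts = 13, seed = 2)
  pooled <- pool_judgements(panel)
  cfg <- psa_config(n_iterations = 2000, seed = 3, distribution_map = list(
    split = dist_dirichlet(c(3, 4.5, 2.5) * 20),
    t = dist_empirical(pooled)))
  res <- run_psa(function(p) {
    c(sum_split = sum(p$split), mild = p$split[1], t = p$t)
  }, cfg)
  s <- res$samples
  expect_true(all(abs(s$value[s$outcome == "sum_split"] - 1) < 1e-12))
  expect_equal(mean(s$value[s$outcome == "mild"]), 0.3, tolerance = 0.01)
  expect_equal(mean(s$value[s$outcome == "t"]), elicited_mean(pooled),
               tolerance = 0.01)
})

test_that("one-way sensitivity analysis varies one parameter only", {
  base <- list(a = 2, b = 10)
  fn <- function(p) c(out = p$a * p$b, other = p$a + p$b)
  # degenerate range reproduces the base three times
  sa0 <- one_way_sa(fn, base, "a", 2, 2)
  expect_equal(sa0$value_low, sa0$value_base)
  expect_equal(sa0$value_high, sa0$value_base)
  sa <- one_way_sa(fn, base, "a", 1, 4)
  expect_equal(sa$value_low[sa$outcome == "out"], 10)
  expect_equal(sa$value_base[sa$outcome == "out"], 20)
  expect_equal(sa$value_high[sa$outcome == "out"], 40)
  # linear outcome varies linearly across the range
  mid <- one_way_sa(fn, base, "a", 1, 3)
  expect_equal(mid$value_base[1], (mid$value_low[1] + mid$value_high[1]) / 2)
  expect_error(one_way_sa(fn, base, "zz", 0, 1), "Unknown parameter")
  expect_error(one_way_sa(fn, base, "a", 3, 4), "bracket")
})

test_that("raising mortality cannot increase expected direct cost", {
  b <- small_test_bundle()
  sc <- scenario_config()
  static <- paincohort:::prepare_model(b, sc)
  params <- paincohort:::base_parameters(b, sc)
  fn <- function(p) paincohort:::evaluate_params(p, static)
  sa <- one_way_sa(fn, params, "monthly_death", 0, 0.05)
  row <- sa[sa$outcome == "direct_cost_usd_mm", ]
  expect_true(row$value_low >= row$value_base)
  expect_true(row$value_base >= row$value_high)
})

test_that("tornado tables rank parameters by outcome swing", {
  base <- list(a = 2, b = 10, c = 1)
  fn <- function(p) c(out = p$a * p$b + p$c)
  ranges <- tibble::tibble(parameter = c("a", "b", "c"),
                           low = c(1, 9, 0), high = c(3, 11, 2))
  tt <- tornado_table(fn, base, ranges)
  expect_equal(tt$parameter[1], "a")  # swing 20 beats 4 and 2
  expect_equal(tt$swing, sort(tt$swing, decreasing = TRUE))
})

test_that("tidy and glance expose the PSA summary and metadata", {
  cfg <- psa_config(n_iterations = 20, seed = 1, distribution_map = list(
    x = dist_beta(0.5, 10)))
  res <- run_psa(function(p) c(out = p$x), cfg)
  td <- tidy(res)
  expect_named(td, c("outcome", "point", "mean", "bci_low", "bci_high"))
  gl <- glance(res)
  expect_equal(gl$n_iterations, 20L)
  expect_equal(gl$n_parameters, 1L)
})
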