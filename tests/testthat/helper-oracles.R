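# Independent oracles and small generators used across the suite.

# Brute-force weighted average over all (expert, bin) pairs with equal
# expert weights: the linear-opinion-pool mean computed without the
# package's pooling path.
brute_force_pooled_mean <- function(panel) {
  experts <- split(panel, panel$expert_id)
  means <- vapply(experts, function(d) sum(d$bin_midpoint * d$weight),
                  numeric(1L))
  mean(means)
}

# Random panel on a shared grid: each expert gets random non-negative
# weights normalized to 1.
random_panel <- function(n_experts, n_bins) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  mid <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  do.call(rbind, lapply(seq_len(n_experts), function(i) {
    w <- runif(n_bins)
    data.frame(expert_id = sprintf("e%02d", i), bin_midpoint = mid,
               weight = w / sum(w))
  }))
}

# Random row-stochastic 4x4 transition matrix with an absorbing death row.
random_transition_matrix <- function() {
  m <- matrix(0, 4L, 4L)
  for (i in 1:3) {
    r <- runif(4L)
    m[i, ] <- r / sum(r)
  }
  m[4L, 4L] <- 1
  transition_matrix(m)
}

# Small bundle used by pipeline tests: full default structure, cheap PSA.
small_test_bundle <- function(seed = 11L) {
  generate_parameter_set(synth_config(seed = seed))
}

# Point mass density at a probability p (single expert).
point_mass_panel <- function(p, n_bins = 21L) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  mid <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w <- numeric(n_bins)
  w[which.min(abs(mid - p))] <- 1
  data.frame(expert_id = "e01", bin_midpoint = mid, weight = w)
}
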