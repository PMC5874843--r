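# Shared in-code fixtures for the test suite.

# Single-element LJ model with zero charges: analytic expectations are easy.
lj_only_model <- function(sigma = 3.4, epsilon = 0.1) {
  energy_model(lj = data.frame(element = "C", sigma = sigma, epsilon = epsilon))
}

# Model under which every energy is exactly zero.
null_model <- function() {
  energy_model(lj = data.frame(element = "*", sigma = 3.4, epsilon = 0))
}

# A small dense builder configuration that reliably reaches its crosslink
# target: 10 chains x 10 monomers (target 20 bridges) in a 36 A cube at
# 4 A separation.
small_build_config <- function(seed = 1L) {
  builder_config(n_chains = 10L, chain_length = 10L,
                 box_lengths = c(36, 36, 36), min_separation = 4,
                 seed = seed)
}

# Invariant checks shared by the network tests and the acceptance suite.
check_crosslink_invariants <- function(mdl) {
  cl <- mdl$crosslinks
  expect_true(all(cl$chain_a != cl$chain_b))
  expect_true(all(cl$formation_distance <= mdl$config$crosslink_cutoff + 1e-9))
  keys <- c(paste(cl$chain_a, cl$site_a), paste(cl$chain_b, cl$site_b))
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(sum(mdl$sites$used), 2L * nrow(cl))
}

random_rotation <- function() {
  u <- stats::rnorm(4)
  gelforge:::quat_to_matrix(u / sqrt(sum(u^2)))
}
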