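# Shared fixtures, built in code. Small configurations keep unit tests
# fast; the acceptance suite builds the full-size session itself.

.fixture_env <- new.env(parent = emptyenv())

# 8 trials of 3-4 s, 30 M1 + 15 SC neurons: enough structure for every
# pipeline stage at a few seconds' cost.
small_config <- function(seed = 11, n_trials = 8,
                         trial_duration_range = c(3, 4),
                         neuron_counts = c(M1 = 30, SC = 15), ...) {
  simulation_config(n_trials = n_trials,
                    trial_duration_range = trial_duration_range,
                    neuron_counts = neuron_counts, seed = seed, ...)
}

small_dataset <- function() {
  if (is.null(.fixture_env$small_ds))
    .fixture_env$small_ds <- make_dataset(small_config())
  .fixture_env$small_ds
}

# Cheap decoder settings for tests that only need plumbing, not accuracy.
tiny_hyperparams <- function(...) {
  decoder_hyperparams(hidden = 12, epochs = 3, lr = 0.01, chunk_len = 300,
                      ...)
}

# A random proper rotation matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

expect_equal_tol <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}

deg2rad_test <- function(x) x * pi / 180
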