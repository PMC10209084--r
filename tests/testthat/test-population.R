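# Population analyses: Wilcoxon contrast, ensemble sweep, single-neuron
# screen, sequence shuffle, permutation test, jaw-correlation control.

# Exhaustive signed-rank oracle: enumerate all 2^n sign assignments.
exact_wilcoxon_p <- function(d, alternative = "two.sided") {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- signs %*% r
  if (alternative == "greater") mean(v_null >= v_obs)
  else if (alternative == "less") mean(v_null <= v_obs)
  else {
    mu <- n * (n + 1) / 4
    mean(abs(v_null - mu) >= abs(v_obs - mu) - 1e-12)
  }
}

test_that("Wilcoxon signed-rank matches exhaustive sign enumeration", {
  # textbook case: differences 1..5, one-sided p = 1/32
  expect_equal(exact_wilcoxon_p(c(1, 2, 3, 4, 5), "greater"), 1 / 32)
  expect_equal(
    stats::wilcox.test(c(1, 2, 3, 4, 5), alternative = "greater",
                       exact = TRUE)$p.value, 1 / 32)
  # random paired data up to 12 pairs, two-sided
  set.seed(14)
  for (n in c(5, 8, 12)) {
    d <- round(stats::rnorm(n, 0.4, 1), 3)
    while (any(d == 0) || any(duplicated(abs(d))))
      d <- round(stats::rnorm(n, 0.4, 1), 3)
    expect_equal(stats::wilcox.test(d, exact = TRUE)$p.value,
                 exact_wilcoxon_p(d), tolerance = 1e-12)
    # and through the package's paired interface
    expect_equal(paired_region_test(d, rep(0, n))$p.value,
                 exact_wilcoxon_p(d), tolerance = 1e-12)
  }
  # degenerate all-zero differences: p = 1 with a warning, not an error
  expect_warning(res <- paired_region_test(1:5 / 10, 1:5 / 10), "degenerate")
  expect_equal(res$p.value, 1)
})

test_that("region comparison separates tuned from untuned populations", {
  # SC-like population carries no tuning at all; M1-like is tuned
  ds <- make_dataset(small_config(seed = 51, tuning_snr = 6,
                                  sc_snr_factor = 0,
                                  neuron_counts = c(M1 = 40, SC = 40)))
  rc <- region_comparison(ds, variables = c("sagittal_flexion", "jaw_pitch",
                                            "middle_width"),
                          n = 40,
                          hyperparams = decoder_hyperparams(
                            hidden = 24, epochs = 20, lr = 0.01),
                          seed = 2, n_eval_folds = 1)
  expect_true(all(rc$table$difference > 0))
  expect_equal(nrow(rc$table), 3)
})

test_that("ensemble sweep bookkeeping: draws, ordering, shape weights", {
  ds <- small_dataset()
  ds <- add_shape_scores(ds, k = 3)
  ec <- ensemble_sweep(ds, sizes = c(2, 5), n_draws = 2,
                       variables = c("jaw_pitch", "shape_pc1", "shape_pc2"),
                       hyperparams = tiny_hyperparams(), seed = 7,
                       n_eval_folds = 1)
  expect_equal(sum(ec$shape_weights), 1, tolerance = 1e-9)
  # draws are without replacement and reproducible under the seed
  for (d in ec$draws) expect_false(any(duplicated(d)))
  ec2 <- ensemble_sweep(ds, sizes = c(2, 5), n_draws = 2,
                        variables = c("jaw_pitch"),
                        hyperparams = tiny_hyperparams(), seed = 7,
                        n_eval_folds = 1)
  expect_identical(ec$draws, ec2$draws)
  # a full-population draw reduces to the standard cross-validation
  pool <- ds$neurons$neuron_id[ds$neurons$region == "M1"]
  ec3 <- ensemble_sweep(ds, sizes = length(pool), n_draws = 1,
                        variables = "jaw_pitch",
                        hyperparams = tiny_hyperparams(), seed = 3,
                        n_eval_folds = 1)
  cv <- cross_validate(ds, "jaw_pitch", ensemble = pool,
                       hyperparams = tiny_hyperparams(), seed = 3,
                       n_eval_folds = 1)
  expect_equal(ec3$table$mean_fvaf, cv$mean_fvaf, tolerance = 1e-12)
  expect_error(ensemble_sweep(ds, sizes = c(5, 1000)), "exceeds")
})

test_that("sequence shuffle is a derangement preserving spike marginals", {
  ds <- small_dataset()
  sh <- sequence_shuffle(ds, seed = 3)
  perm <- attr(sh, "permutation")
  expect_true(all(perm != seq_along(perm)))
  expect_setequal(perm, seq_along(ds$markers))
  # reproducible
  expect_identical(attr(sequence_shuffle(ds, seed = 3), "permutation"), perm)
  # per-neuron totals preserved up to truncation; untruncated pairs exact
  for (tr in seq_along(perm)) {
    src <- perm[tr]
    if (nrow(ds$kinematics[[tr]]) >= nrow(ds$kinematics[[src]])) {
      a <- table(ds$spikes$neuron_id[ds$spikes$trial == src])
      b <- table(sh$spikes$neuron_id[sh$spikes$trial == tr])
      expect_equal(sum(b), sum(a))
    }
    # kinematics and spikes stay mutually consistent in length
    t_max <- nrow(sh$kinematics[[tr]]) / 200
    expect_true(all(sh$spikes$spike_time_s[sh$spikes$trial == tr] < t_max))
  }
  # two sequences: the only derangement is the swap
  ds2 <- make_dataset(small_config(seed = 52, n_trials = 7))
  # (7 trials: just check the derangement property holds there too)
  expect_true(all(attr(sequence_shuffle(ds2, seed = 1),
                       "permutation") != 1:7))
})

test_that("permutation test: exchangeable null, extreme separation, enumeration oracle", {
  set.seed(31)
  vals <- stats::rnorm(20)
  # observed identical to shuffled: statistic 0, p near 1
  pt <- permutation_test(vals, vals, n_perm = 500, seed = 1)
  expect_equal(pt$statistics[1], 0)
  expect_gt(pt$p_values[1], 0.4)
  expect_equal(pt$n_iterations, 1)
  # complete separation attains the smoothed lower bound 1/(n_perm+1)
  pt2 <- permutation_test(vals + 100, vals, n_perm = 499, seed = 2)
  expect_equal(pt2$p_max, 1 / 500)
  # 3-vs-3 toy case against exhaustive enumeration over all 20 splits
  obs <- c(0.9, 0.7, 0.5); sh <- c(0.2, 0.1, 0.3)
  tq <- function(x) mean(x[x >= stats::quantile(x, 0.75, names = FALSE)])
  pooled <- c(obs, sh)
  splits <- utils::combn(6, 3)
  null <- apply(splits, 2, function(i) tq(pooled[i]) - tq(pooled[-i]))
  p_exact <- mean(null >= tq(obs) - tq(sh))
  pt3 <- permutation_test(obs, sh, n_perm = 4000, seed = 3)
  expect_lt(abs(pt3$p_values[1] - p_exact), 0.02)
  # multiple iterations: reported p is the maximum
  pt4 <- permutation_test(vals + 1, list(vals, vals - 2), n_perm = 300,
                          seed = 4)
  expect_equal(pt4$p_max, max(pt4$p_values))
  expect_warning(permutation_test(obs, sh, n_perm = 50), "coarse")
})

test_that("permutation p-values are uniform under a global null", {
  set.seed(77)
  ps <- replicate(200, {
    permutation_test(stats::rnorm(12), stats::rnorm(12), n_perm = 199,
                     seed = sample.int(1e6, 1))$p_values[1]
  })
  # p-values live on a grid of 1/200: the KS tie warning is expected
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-neuron screen applies the rate filter and pools positive scores", {
  ds <- small_dataset()
  sn <- single_neuron_screen(ds, rate_threshold = 3, n_neurons = 3,
                             variables = c("jaw_pitch", "sagittal_flexion"),
                             n_test_folds = 2,
                             hyperparams = tiny_hyperparams(), seed = 5)
  expect_length(sn$neurons, 3)
  expect_true(all(sn$rates > 3))
  expect_true(all(sn$positive_fvaf > 0))
  expect_equal(nrow(sn$accuracies), 6)
  # a neuron below the rate threshold is never selected
  slow <- names(which(table(ds$spikes$neuron_id) /
                        sum(trial_durations(ds)) <= 3))
  expect_false(any(slow %in% sn$neurons))
  expect_error(single_neuron_screen(ds, rate_threshold = 1e6), "no neuron")
})

test_that("jaw-correlation control windows behave as specified", {
  fr <- 200
  t <- seq(0, 10, by = 1 / fr)[-1]
  jaw <- sin(2 * pi * 1.5 * t)
  # tongue variable identical to jaw pitch: |r| = 1 in every window
  jc <- jaw_correlation_control(jaw, jaw, jaw, window_len = 200, step = 50)
  expect_equal_tol(abs(jc$windows$r), 1, 1e-9)
  # window count arithmetic
  expect_equal(nrow(jc$windows) + jc$n_skipped,
               floor((length(t) - 200) / 50) + 1)
  # a well-decoded variable orthogonal to the jaw keeps its accuracy in
  # the least-correlated windows
  set.seed(9)
  ortho <- cos(2 * pi * 0.75 * t) * sin(2 * pi * 3.1 * t)
  decoded <- ortho + stats::rnorm(length(t), sd = 0.1 * stats::sd(ortho))
  jc2 <- jaw_correlation_control(decoded, ortho, jaw,
                                 window_len = 200, step = 50)
  expect_gt(jc2$low_r_quartile$mean_fvaf, 0.5)
})
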