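# Population-level analyses: region comparison, ensemble-size sweep,
# single-neuron screening with the sequence-shuffle permutation test,
# and the tongue-jaw correlation control.

sample_neurons <- function(dataset, region, n, seed, stream = 21) {
  pool <- dataset$neurons$neuron_id[dataset$neurons$region == region]
  if (n > length(pool))
    stop(sprintf("requested %d neurons but region %s has only %d",
                 n, region, length(pool)))
  with_seed(substream_seed(seed, stream, n), sample(pool, n))
}

#' Compare decoding accuracy between cortical regions
#'
#' Decodes each variable from equally sized ensembles (default n = 55)
#' drawn from each region on identical kinematic targets, then compares
#' the per-variable mean FVAFs with a paired two-sided Wilcoxon
#' signed-rank test (exact null for <= 20 pairs).
#'
#' @param dataset a `feeding_dataset` with both regions.
#' @param variables variables to decode (default the 7 standard tongue
#'   variables).
#' @param n ensemble size per region (default 55).
#' @param hyperparams,seed,n_eval_folds passed to [cross_validate()].
#' @return List of class `region_comparison`: `table` (variable,
#'   fvaf_M1, fvaf_SC, difference), `wilcoxon` (htest or degenerate
#'   summary), ensembles used.
#' @export
region_comparison <- function(dataset, variables = standard_variables(),
                              n = 55, hyperparams = decoder_hyperparams(),
                              seed = 1, n_eval_folds = NULL) {
  ens <- list(M1 = sample_neurons(dataset, "M1", n, seed, stream = 21),
              SC = sample_neurons(dataset, "SC", n, seed, stream = 22))
  folds <- make_folds(seq_along(dataset$markers), seed = seed)
  res <- lapply(c("M1", "SC"), function(rg) {
    vapply(variables, function(v)
      cross_validate(dataset, v, ensemble = ens[[rg]],
                     hyperparams = hyperparams, seed = seed, folds = folds,
                     n_eval_folds = n_eval_folds)$mean_fvaf, numeric(1))
  })
  tab <- data.frame(variable = variables, fvaf_M1 = res[[1]],
                    fvaf_SC = res[[2]],
                    difference = res[[1]] - res[[2]], row.names = NULL)
  wt <- paired_region_test(tab$fvaf_M1, tab$fvaf_SC)
  structure(list(table = tab, wilcoxon = wt, ensembles = ens, n = n,
                 seed = seed), class = "region_comparison")
}

#' Paired two-sided Wilcoxon signed-rank test between regions
#'
#' Exact null for <= 20 pairs (no ties/zeros); degenerate input (all
#' paired differences zero) is reported as p = 1 with a warning rather
#' than an error.
#'
#' @param fvaf_a,fvaf_b paired per-variable accuracies.
#' @return An `htest`-like list with at least `p.value` and `statistic`.
#' @export
paired_region_test <- function(fvaf_a, fvaf_b) {
  d <- fvaf_a - fvaf_b
  if (all(abs(d) < 1e-12)) {
    warning("all paired differences are zero: Wilcoxon test degenerate; p = 1")
    return(list(p.value = 1, statistic = NA_real_, degenerate = TRUE))
  }
  stats::wilcox.test(fvaf_a, fvaf_b, paired = TRUE,
                     exact = length(d) <= 20)
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("Region comparison (n = %d neurons each):\n", x$n))
  print(x$table, digits = 3)
  cat(sprintf("  mean difference (M1 - SC): %.3f; Wilcoxon signed-rank p = %.4g\n",
              mean(x$table$difference), x$wilcoxon$p.value))
  invisible(x)
}

#' Decoding accuracy as a function of ensemble size
#'
#' Randomly draws without-replacement sub-populations at each ensemble
#' size and reports cross-validated mean FVAF per size. Kinematic
#' variables are averaged unweighted; shape variables are averaged
#' weighted by each component's fraction of shape variance explained.
#'
#' @param dataset a `feeding_dataset`.
#' @param sizes increasing ensemble sizes (default
#'   `c(1, 2, 5, 10, 15, 25, 35, 50, 75, 100)`).
#' @param n_draws random draws per size.
#' @param variables variables to decode; names starting `shape_pc` are
#'   treated as shape variables.
#' @param region neuron pool (default M1).
#' @param hyperparams,seed,n_eval_folds passed to [cross_validate()].
#' @return List of class `ensemble_curve`: `table` (size, draw,
#'   variable_type, mean_fvaf), `summary` (per size x type: mean, sd),
#'   `draws` (neuron id sets).
#' @export
ensemble_sweep <- function(dataset,
                           sizes = c(1, 2, 5, 10, 15, 25, 35, 50, 75, 100),
                           n_draws = 10, variables = standard_variables(),
                           region = "M1",
                           hyperparams = decoder_hyperparams(), seed = 1,
                           n_eval_folds = NULL) {
  stopifnot(n_draws >= 1, all(diff(sizes) > 0))
  pool <- dataset$neurons$neuron_id[dataset$neurons$region == region]
  if (max(sizes) > length(pool))
    stop(sprintf("max ensemble size %d exceeds the %d-neuron %s pool",
                 max(sizes), length(pool), region))
  is_shape <- grepl("^shape_pc", variables)
  shape_w <- NULL
  if (any(is_shape)) {
    if (is.null(dataset$shape_space))
      stop("shape variables requested: run add_shape_scores() first")
    k_idx <- as.integer(sub("^shape_pc", "", variables[is_shape]))
    w <- dataset$shape_space$var_explained[k_idx]
    shape_w <- w / sum(w)
  }
  folds <- make_folds(seq_along(dataset$markers), seed = seed)
  rows <- list(); draws <- list()
  for (s in sizes) {
    for (d in seq_len(n_draws)) {
      ids <- with_seed(substream_seed(seed, 23, s * 1000 + d),
                       sample(pool, s))
      ids <- pool[sort(match(ids, pool))]  # canonical order; full draw == pool
      draws[[sprintf("size%d_draw%d", s, d)]] <- ids
      fv <- vapply(variables, function(v)
        cross_validate(dataset, v, ensemble = ids, hyperparams = hyperparams,
                       seed = seed, folds = folds,
                       n_eval_folds = n_eval_folds)$mean_fvaf, numeric(1))
      if (any(!is_shape))
        rows[[length(rows) + 1]] <- data.frame(
          size = s, draw = d, variable_type = "kinematic",
          mean_fvaf = mean(fv[!is_shape]))
      if (any(is_shape))
        rows[[length(rows) + 1]] <- data.frame(
          size = s, draw = d, variable_type = "shape",
          mean_fvaf = sum(shape_w * fv[is_shape]))
    }
  }
  tab <- do.call(rbind, rows)
  agg_m <- stats::aggregate(mean_fvaf ~ size + variable_type, tab, mean)
  agg_s <- stats::aggregate(mean_fvaf ~ size + variable_type, tab, stats::sd)
  names(agg_m)[3] <- "mean"; names(agg_s)[3] <- "sd"
  structure(list(table = tab, summary = merge(agg_m, agg_s),
                 draws = draws, sizes = sizes, shape_weights = shape_w,
                 seed = seed), class = "ensemble_curve")
}

#' @export
print.ensemble_curve <- function(x, ...) {
  cat("Ensemble-size sweep:\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
plot.ensemble_curve <- function(x, ...) {
  s <- x$summary
  types <- unique(s$variable_type)
  cols <- c(kinematic = "steelblue", shape = "darkorange")
  graphics::plot(range(s$size), range(s$mean, na.rm = TRUE), type = "n",
                 xlab = "ensemble size (neurons)", ylab = "mean FVAF", ...)
  for (ty in types) {
    sub <- s[s$variable_type == ty, ]
    sub <- sub[order(sub$size), ]
    graphics::lines(sub$size, sub$mean, col = cols[[ty]], lwd = 2)
    graphics::points(sub$size, sub$mean, col = cols[[ty]], pch = 16)
  }
  graphics::legend("bottomright", legend = types, col = cols[types], lwd = 2)
  invisible(x)
}

#' Single-neuron decoding screen
#'
#' Trains single-neuron decoders for a subsample of neurons passing a
#' mean-rate filter (default > 3 spikes/s), on a reduced scheme in which
#' 3 of the rotating folds are randomly selected as test folds. Pools
#' per-variable accuracies across neurons and retains the positive FVAF
#' values (the right tail of the performance distribution).
#'
#' @param dataset a `feeding_dataset`.
#' @param rate_threshold minimum mean firing rate, spikes/s.
#' @param n_neurons neurons to screen (default 40).
#' @param variables variables to decode per neuron.
#' @param selection `"random"` among rate-passing neurons, or `"top"`
#'   (post hoc best performers by pooled accuracy).
#' @param region neuron pool.
#' @param n_test_folds test folds per neuron (default 3).
#' @param hyperparams,seed passed to the decoders.
#' @return List of class `single_neuron_screen`: `accuracies` (long
#'   table: neuron, variable, mean FVAF), `positive_fvaf` (the pooled
#'   positive values), `neurons` screened, rates.
#' @export
single_neuron_screen <- function(dataset, rate_threshold = 3, n_neurons = 40,
                                 variables = standard_variables(),
                                 selection = c("random", "top"),
                                 region = "M1", n_test_folds = 3,
                                 hyperparams = decoder_hyperparams(),
                                 seed = 1) {
  selection <- match.arg(selection)
  pool <- dataset$neurons$neuron_id[dataset$neurons$region == region]
  dur <- sum(trial_durations(dataset))
  counts <- table(factor(dataset$spikes$neuron_id, levels = pool))
  rates <- as.numeric(counts) / dur
  names(rates) <- pool
  passing <- pool[rates > rate_threshold]
  if (length(passing) == 0)
    stop(sprintf("no neuron passes the %g spikes/s rate filter",
                 rate_threshold))
  if (length(passing) < n_neurons) {
    warning(sprintf("only %d neurons pass the rate filter; screening all",
                    length(passing)))
    n_neurons <- length(passing)
  }
  cand <- if (selection == "random")
    with_seed(substream_seed(seed, 31, 0), sample(passing, n_neurons))
  else passing

  folds <- make_folds(seq_along(dataset$markers), seed = seed)
  test_folds <- with_seed(substream_seed(seed, 32, 0),
                          sample(folds$test_folds, n_test_folds))
  rows <- list()
  for (nid in cand) {
    for (v in variables) {
      # reduced scheme: train/test only on the randomly selected folds
      cv <- cross_validate(dataset, v, ensemble = nid,
                           hyperparams = hyperparams, seed = seed,
                           folds = folds, eval_folds = test_folds)
      rows[[length(rows) + 1]] <- data.frame(
        neuron_id = nid, variable = v, mean_fvaf = cv$mean_fvaf)
    }
  }
  acc <- do.call(rbind, rows)
  if (selection == "top" && length(cand) > n_neurons) {
    by_neuron <- stats::aggregate(mean_fvaf ~ neuron_id, acc, max)
    keep <- by_neuron$neuron_id[order(-by_neuron$mean_fvaf)][seq_len(n_neurons)]
    acc <- acc[acc$neuron_id %in% keep, , drop = FALSE]
    cand <- keep
  }
  structure(list(accuracies = acc,
                 positive_fvaf = acc$mean_fvaf[acc$mean_fvaf > 0],
                 neurons = cand, rates = rates[cand],
                 test_folds = test_folds, rate_threshold = rate_threshold,
                 seed = seed), class = "single_neuron_screen")
}

#' @export
print.single_neuron_screen <- function(x, ...) {
  cat(sprintf("Single-neuron screen: %d neurons (> %g sp/s), %d variable scores, %d positive\n",
              length(x$neurons), x$rate_threshold, nrow(x$accuracies),
              length(x$positive_fvaf)))
  if (length(x$positive_fvaf))
    cat(sprintf("  positive FVAF: median %.3f, max %.3f\n",
                stats::median(x$positive_fvaf), max(x$positive_fvaf)))
  invisible(x)
}

#' Shuffle the neural-kinematic pairing across feeding sequences
#'
#' Applies a derangement (no sequence keeps its own pairing) to the
#' trial labels of the neural data, so the spikes of sequence X are
#' paired with the kinematics of sequence Y. Length mismatches are
#' resolved by truncating both members to the shorter duration.
#' Marginal spike statistics are preserved.
#'
#' @param dataset a `feeding_dataset`.
#' @param seed RNG seed for the derangement.
#' @return A new `feeding_dataset` with permuted pairing; the applied
#'   permutation is attached as attribute `"permutation"`.
#' @export
sequence_shuffle <- function(dataset, seed = 1) {
  n <- length(dataset$markers)
  if (n < 2) stop("need at least 2 feeding sequences to shuffle")
  perm <- with_seed(substream_seed(seed, 41, 0), {
    if (n == 2) c(2L, 1L)
    else {
      repeat {
        p <- sample(n)
        if (all(p != seq_len(n))) break
      }
      p
    }
  })
  out <- dataset
  fr <- dataset$config$frame_rate
  for (tr in seq_len(n)) {
    src <- perm[tr]  # neural data taken from sequence `src`
    nf <- min(n_frames(dataset$markers[[tr]]),
              n_frames(dataset$markers[[src]]))
    t_max <- nf / fr
    # truncate kinematics of trial tr
    out$kinematics[[tr]] <- dataset$kinematics[[tr]][seq_len(nf), ,
                                                     drop = FALSE]
    pos <- dataset$markers[[tr]]$positions[seq_len(nf), , , drop = FALSE]
    out$markers[[tr]] <- marker_trajectories(pos,
                                             dataset$markers[[tr]]$markers,
                                             fr, tr)
    sp <- dataset$spikes[dataset$spikes$trial == src &
                           dataset$spikes$spike_time_s < t_max, , drop = FALSE]
    sp$trial <- tr
    out$spikes <- if (tr == 1) sp else rbind(out$spikes, sp)
  }
  out$spikes <- spike_events(out$spikes[order(out$spikes$trial), ,
                                        drop = FALSE])
  attr(out, "permutation") <- perm
  out
}

#' Two-sample permutation test with a top-quartile statistic
#'
#' For each shuffle iteration, tests observed vs shuffled accuracy
#' values: the statistic is the difference in the mean of the fourth
#' (top) quartile (values at or above the 75th percentile, linear
#' interpolation); the null is built by `n_perm` random label
#' permutations, and `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#' The reported p-value is conservatively the maximum over iterations.
#'
#' @param observed numeric vector of observed accuracies.
#' @param shuffled a numeric vector (one iteration) or list of vectors
#'   (one per shuffle iteration, default 10 iterations upstream).
#' @param n_perm permutations per iteration (default 10000).
#' @param seed RNG seed.
#' @return List of class `permutation_test`: `p_values` per iteration,
#'   `p_max`, observed statistic per iteration, null summaries.
#' @export
permutation_test <- function(observed, shuffled, n_perm = 10000, seed = 1) {
  if (!is.list(shuffled)) shuffled <- list(shuffled)
  stopifnot(length(observed) > 0, all(lengths(shuffled) > 0))
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  top_quartile_mean <- function(x) {
    q <- stats::quantile(x, 0.75, type = 7, names = FALSE)
    mean(x[x >= q])
  }
  res <- lapply(seq_along(shuffled), function(it) {
    sh <- shuffled[[it]]
    obs_stat <- top_quartile_mean(observed) - top_quartile_mean(sh)
    pooled <- c(observed, sh)
    n_obs <- length(observed)
    null <- with_seed(substream_seed(seed, 43, it), {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample(length(pooled), n_obs)
        top_quartile_mean(pooled[idx]) - top_quartile_mean(pooled[-idx])
      }, numeric(1))
    })
    list(stat = obs_stat, p = (1 + sum(null >= obs_stat)) / (n_perm + 1),
         null_mean = mean(null), null_sd = stats::sd(null))
  })
  structure(list(p_values = vapply(res, `[[`, numeric(1), "p"),
                 p_max = max(vapply(res, `[[`, numeric(1), "p")),
                 statistics = vapply(res, `[[`, numeric(1), "stat"),
                 null_mean = vapply(res, `[[`, numeric(1), "null_mean"),
                 null_sd = vapply(res, `[[`, numeric(1), "null_sd"),
                 n_perm = n_perm, n_iterations = length(shuffled)),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations, %d shuffle iteration%s):\n",
              x$n_perm, x$n_iterations, if (x$n_iterations > 1) "s" else ""))
  cat(sprintf("  observed top-quartile-mean difference: %s\n",
              paste(sprintf("%.3f", x$statistics), collapse = ", ")))
  cat(sprintf("  p per iteration: %s; reported (max) p = %.4g\n",
              paste(sprintf("%.4g", x$p_values), collapse = ", "), x$p_max))
  invisible(x)
}

#' Tongue-jaw correlation control
#'
#' Slides a window along aligned decoded/truth/jaw-pitch series; per
#' window computes the Pearson correlation of the tongue variable with
#' jaw pitch and the windowed FVAF of the decoded trace. Summarises the
#' accuracy distribution within the lowest-|r| quartile of windows: high
#' FVAF there shows decoding is not explained by tongue-jaw coupling.
#'
#' @param decoded,truth decoded and ground-truth series (same variable).
#' @param jaw jaw pitch series, same length.
#' @param window_len window length in samples (default 200 = 1 s at
#'   200 Hz).
#' @param step step between windows in samples (default 50 = 0.25 s).
#' @return List of class `jaw_control`: `windows` (start, r, fvaf),
#'   `low_r_quartile` (accuracy stats in the least-correlated quartile),
#'   `n_skipped` (constant windows).
#' @export
jaw_correlation_control <- function(decoded, truth, jaw, window_len = 200,
                                    step = 50) {
  n <- length(truth)
  stopifnot(length(decoded) == n, length(jaw) == n, window_len <= n,
            step >= 1)
  starts <- seq(1, n - window_len + 1, by = step)
  rows <- list(); skipped <- 0
  for (s in starts) {
    idx <- s:(s + window_len - 1)
    if (stats::sd(truth[idx]) < 1e-12 || stats::sd(jaw[idx]) < 1e-12) {
      skipped <- skipped + 1
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      start = s,
      r = stats::cor(truth[idx], jaw[idx]),
      fvaf = fvaf(decoded[idx], truth[idx]))
  }
  win <- do.call(rbind, rows)
  if (is.null(win)) stop("all windows were constant; nothing to summarise")
  thr <- stats::quantile(abs(win$r), 0.25, names = FALSE)
  low <- win[abs(win$r) <= thr, , drop = FALSE]
  structure(list(windows = win,
                 low_r_quartile = list(
                   n = nrow(low), r_threshold = thr,
                   mean_fvaf = mean(low$fvaf),
                   median_fvaf = stats::median(low$fvaf)),
                 n_skipped = skipped,
                 window_len = window_len, step = step),
            class = "jaw_control")
}

#' @export
print.jaw_control <- function(x, ...) {
  cat(sprintf("Tongue-jaw correlation control: %d windows (%d skipped)\n",
              nrow(x$windows), x$n_skipped))
  cat(sprintf("  lowest-|r| quartile (|r| <= %.2f, n = %d): mean FVAF %.3f, median %.3f\n",
              x$low_r_quartile$r_threshold, x$low_r_quartile$n,
              x$low_r_quartile$mean_fvaf, x$low_r_quartile$median_fvaf))
  invisible(x)
}
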