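# Causal sequence-to-sequence decoding of kinematic and shape variables
# from binned population spiking.

#' Bin spike times into a neuron x bin count matrix
#'
#' Half-open bins `[t, t + width)` aligned to the kinematic frame grid
#' (at 200 Hz and 5 ms bins, one bin per frame). Total spike count is
#' preserved.
#'
#' @param spikes a `spike_events` table (one trial) or a data.frame with
#'   `neuron_id` and `spike_time_s`.
#' @param neuron_ids neurons to include (rows, in this order); defaults
#'   to all neurons present.
#' @param bin_width_ms bin width, ms (default 5).
#' @param t_end trial span end, seconds; the number of bins is
#'   `round(t_end / bin_width)`.
#' @return Integer matrix, neurons x bins, with neuron id rownames.
#' @export
bin_spikes <- function(spikes, neuron_ids = NULL, bin_width_ms = 5, t_end) {
  stopifnot(bin_width_ms > 0)
  dt <- bin_width_ms / 1000
  n_bins <- round(t_end / dt)
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(spikes$neuron_id))
  bad <- spikes$spike_time_s < 0 | spikes$spike_time_s >= n_bins * dt
  if (any(bad))
    stop(sprintf("%d spike(s) outside the trial span [0, %g): first at t=%g s",
                 sum(bad), n_bins * dt, spikes$spike_time_s[which(bad)[1]]))
  m <- matrix(0L, length(neuron_ids), n_bins,
              dimnames = list(neuron_ids, NULL))
  sub <- spikes[spikes$neuron_id %in% neuron_ids, , drop = FALSE]
  if (nrow(sub)) {
    bin <- floor(sub$spike_time_s / dt) + 1L
    tab <- table(factor(sub$neuron_id, levels = neuron_ids), bin)
    m[, as.integer(colnames(tab))] <- m[, as.integer(colnames(tab))] +
      matrix(as.integer(tab), nrow = length(neuron_ids))
  }
  m
}

#' Seven-fold cross-validation partition
#'
#' Randomly assigns trials to `n_folds` folds of (as near as possible)
#' equal size. One fold is reserved for hyperparameter selection and is
#' never used as a test fold; the remaining folds rotate as test sets,
#' with training on all other trials (for 28 trials: 6 test folds of 4,
#' train sets of 24).
#'
#' @param trial_ids vector of trial identifiers.
#' @param n_folds number of folds (default 7).
#' @param seed RNG seed for the assignment.
#' @return List of class `fold_partition`: `assignment` (trial -> fold),
#'   `hyper_fold` (the held-out fold id), `test_folds` (the rotating
#'   evaluation fold ids).
#' @export
make_folds <- function(trial_ids, n_folds = 7, seed = 1) {
  n <- length(trial_ids)
  if (n < n_folds)
    stop(sprintf("%d trials cannot be split into %d folds", n, n_folds))
  fold <- with_seed(substream_seed(seed, 11, 0),
                    sample(rep(seq_len(n_folds), length.out = n)))
  names(fold) <- as.character(trial_ids)
  structure(list(assignment = fold, hyper_fold = n_folds,
                 test_folds = seq_len(n_folds - 1), trial_ids = trial_ids),
            class = "fold_partition")
}

#' @export
print.fold_partition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf("Fold partition: %d trials in %d folds (sizes %s); fold %d held out for hyperparameters\n",
              length(x$assignment), length(sizes),
              paste(sizes, collapse = "/"), x$hyper_fold))
  invisible(x)
}

#' Fraction of variance accounted for
#'
#' `1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)`. Equals 1
#' for perfect prediction, 0 for predicting the mean, and is negative
#' for predictions worse than the mean.
#'
#' @param pred,truth numeric vectors of equal length (>= 2 samples).
#' @return A single numeric score (`NA` with a warning when the truth is
#'   constant, where the metric is undefined).
#' @export
fvaf <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  sst <- sum((truth - mean(truth))^2)
  if (sst < 1e-300) {
    warning("constant truth series: FVAF undefined")
    return(NA_real_)
  }
  1 - sum((truth - pred)^2) / sst
}

#' Default decoder hyperparameters
#'
#' @param hidden LSTM hidden units (default 200).
#' @param epochs training epochs over the train set.
#' @param lr Adam learning rate.
#' @param batch_size training sequences per mini-batch.
#' @param clip global gradient-norm clip.
#' @param weight_decay decoupled (AdamW-style) L2 decay on the weight
#'   matrices; regularises against memorising training sequences.
#' @param chunk_len training sequences are split into chunks of at most
#'   this many bins (default 400, i.e. 2 s at 5 ms bins) so each epoch
#'   makes many optimizer updates; the hidden state is re-initialised per
#'   chunk during training only — prediction always unrolls whole trials.
#' @param val_frac fraction of each training trial held out as a
#'   mid-trial validation segment for epoch selection (early stopping);
#'   the returned model is the epoch with the lowest validation MSE,
#'   which keeps decoders from memorising uninformative inputs. The
#'   segment sits at mid-trial, where feeding behaviour is active. `0`
#'   disables early stopping.
#' @return Named list.
#' @export
decoder_hyperparams <- function(hidden = 200, epochs = 20, lr = 0.01,
                                batch_size = 16, clip = 5, chunk_len = 400,
                                weight_decay = 0.02, val_frac = 0.15) {
  list(hidden = hidden, epochs = epochs, lr = lr,
       batch_size = batch_size, clip = clip, chunk_len = chunk_len,
       weight_decay = weight_decay, val_frac = val_frac)
}

# Split paired input/target sequences into training chunks of <= chunk_len.
chunk_sequences <- function(x, y, chunk_len) {
  xs <- list(); ys <- list()
  for (i in seq_along(x)) {
    Tn <- ncol(x[[i]])
    starts <- seq(1, Tn, by = chunk_len)
    for (s in starts) {
      e <- min(s + chunk_len - 1, Tn)
      if (e - s + 1 < 10) next  # skip degenerate tail chunks
      xs[[length(xs) + 1]] <- x[[i]][, s:e, drop = FALSE]
      ys[[length(ys) + 1]] <- y[[i]][s:e]
    }
  }
  list(x = xs, y = ys)
}

#' Train a causal LSTM decoder for one variable
#'
#' Sequence-to-sequence regression from binned spikes (neurons x bins)
#' to a per-bin kinematic/shape variable. Inputs are z-scored per neuron
#' and the target is z-scored, both with training-set statistics;
#' predictions are returned on the original scale. Training is
#' deterministic given `seed`. Loss is the mean squared error over all
#' training bins.
#'
#' @param x list of neuron x bin count matrices (one per training trial),
#'   all with identical neuron id rownames.
#' @param y list of numeric target vectors, lengths matching the bin
#'   counts.
#' @param hyperparams list from [decoder_hyperparams()].
#' @param seed integer training seed (weight init + batch order).
#' @return An object of class `lstm_decoder`.
#' @export
lstm_decoder <- function(x, y, hyperparams = decoder_hyperparams(), seed = 1) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  stopifnot(length(x) >= 1, length(x) == length(y))
  ids <- rownames(x[[1]])
  if (is.null(ids)) stop("binned input matrices must have neuron id rownames")
  for (i in seq_along(x)) {
    if (!identical(rownames(x[[i]]), ids))
      stop("all training matrices must share the same neuron ids")
    if (any(!is.finite(x[[i]])) || any(!is.finite(y[[i]])))
      stop(sprintf("non-finite values in training trial %d", i))
    if (ncol(x[[i]]) != length(y[[i]]))
      stop(sprintf("trial %d: %d bins but %d target samples",
                   i, ncol(x[[i]]), length(y[[i]])))
  }
  hp <- utils::modifyList(decoder_hyperparams(), hyperparams)
  all_x <- do.call(cbind, x)
  mu_x <- rowMeans(all_x)
  sd_x <- apply(all_x, 1, stats::sd)
  sd_x[sd_x < 1e-12] <- 1
  all_y <- unlist(y)
  mu_y <- mean(all_y)
  sd_y <- stats::sd(all_y)
  if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1
  xz <- lapply(x, function(m) (m - mu_x) / sd_x)
  yz <- lapply(y, function(v) (v - mu_y) / sd_y)
  # mid-trial validation segment of each trial for epoch selection
  vf <- hp$val_frac %||% 0
  xv <- list(); yv <- list()
  if (vf > 0) {
    xt <- list(); yt <- list()
    for (i in seq_along(xz)) {
      nb <- ncol(xz[[i]])
      len <- max(20, ceiling(vf * nb))
      if (nb < 3 * len) {  # too short to split: train only
        xt[[length(xt) + 1]] <- xz[[i]]
        yt[[length(yt) + 1]] <- yz[[i]]
        next
      }
      v0 <- floor(nb / 2)
      vidx <- (v0 + 1):(v0 + len)
      xv[[length(xv) + 1]] <- xz[[i]][, vidx, drop = FALSE]
      yv[[length(yv) + 1]] <- yz[[i]][vidx]
      xt[[length(xt) + 1]] <- xz[[i]][, seq_len(v0), drop = FALSE]
      yt[[length(yt) + 1]] <- yz[[i]][seq_len(v0)]
      xt[[length(xt) + 1]] <- xz[[i]][, (v0 + len + 1):nb, drop = FALSE]
      yt[[length(yt) + 1]] <- yz[[i]][(v0 + len + 1):nb]
    }
    xz <- xt; yz <- yt
  }
  if (!is.null(hp$chunk_len) && is.finite(hp$chunk_len)) {
    ch <- chunk_sequences(xz, yz, hp$chunk_len)
    xz <- ch$x; yz <- ch$y
  }
  fit <- lstm_train_cpp(xz, yz, as.integer(hp$hidden), as.integer(hp$epochs),
                        hp$lr, as.integer(hp$batch_size), hp$clip,
                        hp$weight_decay %||% 0,
                        as.integer(substream_seed(seed, 13, 0) %% 2^31),
                        xv, yv)
  structure(list(weights = fit$weights, loss = fit$loss,
                 val_loss = fit$val_loss,
                 neuron_ids = ids, mu_x = mu_x, sd_x = sd_x,
                 mu_y = mu_y, sd_y = sd_y, hyperparams = hp, seed = seed),
            class = "lstm_decoder")
}

#' @export
print.lstm_decoder <- function(x, ...) {
  cat(sprintf("Causal LSTM decoder: %d neurons -> 1 variable, %d hidden units\n",
              length(x$neuron_ids), x$hyperparams$hidden))
  cat(sprintf("  trained %d epochs, final train MSE (z-scored) %.4f\n",
              length(x$loss), utils::tail(x$loss, 1)))
  invisible(x)
}

#' Causal prediction from a trained decoder
#'
#' Stateful stepwise unrolling: the prediction at bin `t` depends only on
#' bins `<= t`. Inputs are keyed by neuron id, so row order need not
#' match training order.
#'
#' @param object an `lstm_decoder`.
#' @param x a neuron x bin count matrix (or list of them) with neuron id
#'   rownames covering the training ids.
#' @param ... unused.
#' @return Numeric vector of predictions (or list of vectors), original
#'   target scale, one value per input bin.
#' @export
predict.lstm_decoder <- function(object, x, ...) {
  one <- function(m) {
    if (is.null(rownames(m))) stop("input matrix must have neuron id rownames")
    if (!all(object$neuron_ids %in% rownames(m)))
      stop("input is missing neurons: ",
           paste(setdiff(object$neuron_ids, rownames(m)), collapse = ", "))
    m <- m[object$neuron_ids, , drop = FALSE]
    z <- (m - object$mu_x) / object$sd_x
    as.numeric(lstm_forward_cpp(object$weights, z)) * object$sd_y + object$mu_y
  }
  if (is.list(x)) lapply(x, one) else one(x)
}

# Binned spike matrices for a set of trials, aligned to the kinematic
# frame grid.
binned_rates <- function(dataset, neuron_ids, trials = NULL) {
  trials <- trials %||% seq_along(dataset$markers)
  dt <- dataset$config$bin_width_ms / 1000
  lapply(trials, function(tr) {
    nf <- n_frames(dataset$markers[[tr]])
    sp <- dataset$spikes[dataset$spikes$trial == tr, , drop = FALSE]
    bin_spikes(sp, neuron_ids, dataset$config$bin_width_ms, t_end = nf * dt)
  })
}

# Target series of `variable` for a set of trials.
variable_series <- function(dataset, variable, trials = NULL) {
  trials <- trials %||% seq_along(dataset$kinematics)
  lapply(trials, function(tr) {
    k <- dataset$kinematics[[tr]]
    if (!variable %in% names(k))
      stop(sprintf("variable '%s' not found; available: %s", variable,
                   paste(setdiff(names(k), "time_s"), collapse = ", ")))
    as.numeric(k[[variable]])
  })
}

#' Append shape PC scores to a dataset's variable tables
#'
#' Fits the Procrustes shape space on all frames of the dataset and adds
#' `shape_pc1..shape_pck` columns to every trial's kinematics table, so
#' shape components can be decoded like any other variable.
#'
#' @param dataset a `feeding_dataset`.
#' @param k number of shape components (default 7).
#' @param space optionally, a pre-fitted `shape_space`.
#' @return The dataset with score columns added and the `shape_space`
#'   attached as `dataset$shape_space`.
#' @export
add_shape_scores <- function(dataset, k = 7, space = NULL) {
  space <- space %||% shape_pca(dataset)
  for (tr in seq_along(dataset$markers)) {
    sc <- project_scores(as_frame_list(dataset$markers[[tr]]$positions),
                         space, k = k)
    for (j in seq_len(k))
      dataset$kinematics[[tr]][[paste0("shape_pc", j)]] <- sc[, j]
  }
  dataset$shape_space <- space
  dataset
}

#' Cross-validated decoding of one variable
#'
#' Implements the rotating-fold scheme: trials are partitioned into 7
#' folds; one fold is reserved for hyperparameter selection and each of
#' the remaining folds serves once as the test set, training on all
#' other trials. The per-fold score is the FVAF on the concatenated test
#' trials of that fold (optionally per trial).
#'
#' @param dataset a `feeding_dataset` (run [add_shape_scores()] first to
#'   decode shape components).
#' @param variable variable name (a kinematics column, e.g. `"roll"` or
#'   `"shape_pc1"`).
#' @param ensemble neuron ids used as decoder input; default all M1
#'   neurons.
#' @param hyperparams list from [decoder_hyperparams()].
#' @param seed seed for fold assignment and training.
#' @param folds optionally a pre-built `fold_partition` (shared across
#'   variables/regions for identical targets).
#' @param n_eval_folds evaluate only the first `n` test folds (the full
#'   scheme uses all 6; reduced-fold schemes are used where many decoders
#'   must be trained).
#' @param eval_folds explicit test fold ids to evaluate (subset of the
#'   partition's rotating folds); overrides `n_eval_folds`.
#' @param keep_predictions retain per-fold prediction traces.
#' @param keep_models retain the per-fold fitted `lstm_decoder` objects
#'   (e.g. for causality checks).
#' @param per_trial_fvaf score per test trial instead of pooled.
#' @return An object of class `decoding_result`: per-fold FVAF, mean,
#'   SD, fold metadata, ensemble ids.
#' @export
cross_validate <- function(dataset, variable, ensemble = NULL,
                           hyperparams = decoder_hyperparams(), seed = 1,
                           folds = NULL, n_eval_folds = NULL,
                           eval_folds = NULL,
                           keep_predictions = FALSE, keep_models = FALSE,
                           per_trial_fvaf = FALSE) {
  trials <- seq_along(dataset$markers)
  ensemble <- ensemble %||%
    dataset$neurons$neuron_id[dataset$neurons$region == "M1"]
  stopifnot(all(ensemble %in% dataset$neurons$neuron_id))
  folds <- folds %||% make_folds(trials, seed = seed)
  if (is.null(eval_folds)) {
    eval_folds <- folds$test_folds
    if (!is.null(n_eval_folds))
      eval_folds <- eval_folds[seq_len(min(n_eval_folds, length(eval_folds)))]
  } else {
    stopifnot(all(eval_folds %in% folds$test_folds))
  }

  x_all <- binned_rates(dataset, ensemble, trials)
  y_all <- variable_series(dataset, variable, trials)

  fold_scores <- numeric(0)
  preds <- list()
  models <- list()
  fold_meta <- list()
  for (f in eval_folds) {
    test_tr <- trials[folds$assignment == f]
    train_tr <- setdiff(trials, test_tr)
    model <- lstm_decoder(x_all[train_tr], y_all[train_tr],
                          hyperparams = hyperparams,
                          seed = substream_seed(seed, 17, f))
    p <- predict(model, x_all[test_tr])
    score <- if (per_trial_fvaf) {
      mean(mapply(fvaf, p, y_all[test_tr]))
    } else {
      fvaf(unlist(p), unlist(y_all[test_tr]))
    }
    fold_scores[as.character(f)] <- score
    fold_meta[[as.character(f)]] <- list(test_trials = test_tr,
                                         train_trials = train_tr)
    if (keep_predictions) preds[[as.character(f)]] <- p
    if (keep_models) models[[as.character(f)]] <- model
  }
  structure(list(variable = variable, fold_fvaf = fold_scores,
                 mean_fvaf = mean(fold_scores),
                 sd_fvaf = stats::sd(fold_scores),
                 folds = folds, fold_meta = fold_meta,
                 ensemble = ensemble, seed = seed,
                 predictions = if (keep_predictions) preds else NULL,
                 models = if (keep_models) models else NULL,
                 hyperparams = utils::modifyList(decoder_hyperparams(),
                                                 hyperparams)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding result: '%s', %d neurons, %d folds\n",
              x$variable, length(x$ensemble), length(x$fold_fvaf)))
  cat(sprintf("  FVAF mean %.3f (SD %.3f); per fold: %s\n",
              x$mean_fvaf, x$sd_fvaf,
              paste(sprintf("%.3f", x$fold_fvaf), collapse = ", ")))
  invisible(x)
}

#' Verify the causality contract of a decoder
#'
#' Asserts that truncating the input after bin `t` leaves predictions at
#' bins `<= t` unchanged, at random truncation points.
#'
#' @param model an `lstm_decoder`.
#' @param x a neuron x bin input matrix.
#' @param n_points number of random truncation points.
#' @param tol tolerance on the prediction difference.
#' @param seed RNG seed for the truncation points.
#' @return `TRUE` invisibly; stops if the contract is violated.
#' @export
check_causality <- function(model, x, n_points = 5, tol = 1e-6, seed = 1) {
  full <- predict(model, x)
  tpts <- with_seed(seed, sample(seq_len(ncol(x) - 1), n_points))
  for (tp in tpts) {
    part <- predict(model, x[, seq_len(tp), drop = FALSE])
    if (max(abs(part - full[seq_len(tp)])) > tol)
      stop(sprintf("causality violation at truncation point %d", tp))
  }
  invisible(TRUE)
}
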