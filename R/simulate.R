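# Synthetic feeding kinematics and encoding-model spike trains.
#
# The generator emulates marker-based feeding trials: a 7-marker tongue
# constellation driven through cyclic gape cycles by smooth latent
# deformation modes (sagittal bending, axial roll, anteroposterior
# protrusion, regional length/width scaling) plus brief swallow-like
# posterior-elevation transients, a mandible pitching in phase with the
# chew cycle, and cortical populations whose firing is lag-tuned to the
# kinematic variables with Poisson spiking.

# Rest constellation (mm, cranial frame; X anterior, Y superior, Z right).
# Arbitrary-but-fixed: order-10 mm inter-marker spacing; real inter-marker
# geometry is animal-specific and not modelled.
rest_constellation <- function() {
  m <- rbind(
    tip                    = c(30,  0,  0),
    anterior_superficial_R = c(22,  2,  6),
    anterior_superficial_L = c(22,  2, -6),
    anterior_deep          = c(20, -4,  0),
    middle_superficial_R   = c(10,  3,  7),
    middle_superficial_L   = c(10,  3, -7),
    posterior_deep         = c( 0, -5,  0))
  colnames(m) <- c("X", "Y", "Z")
  m
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic feeding-session generator.
#' Defaults emulate one recorded session: 28 trials of 6-10 s at 200 Hz
#' with ~1.5 Hz chewing, and M1-like (100 neurons, motor-like negative
#' lags) and SC-like (55 neurons, extra positive lag, weaker tuning)
#' populations.
#'
#' @param n_trials number of trials (default 28).
#' @param trial_duration_range min/max trial duration, seconds.
#' @param frame_rate kinematic sampling rate, Hz; must tie exactly to the
#'   5 ms spike bins (`frame_rate * bin_width_ms == 1000`).
#' @param bin_width_ms spike bin width, ms (default 5).
#' @param chew_frequency nominal chew rate, Hz.
#' @param chew_jitter relative cycle-to-cycle frequency jitter.
#' @param deformation_amplitudes named vector: `flexion` and `roll` in
#'   degrees, `protrusion`, `length`, `width` and `swallow` in mm. All
#'   must be non-negative.
#' @param swallow_rate expected swallow-like events per trial.
#' @param jaw_pitch_amplitude peak mandible pitch excursion, degrees.
#' @param neuron_counts named vector `c(M1 = , SC = )`.
#' @param tuning_snr dimensionless tuning gain of the encoding model
#'   (M1-like population).
#' @param sc_snr_factor multiplier (< 1) applied to `tuning_snr` for the
#'   SC-like population.
#' @param sc_lag_offset_ms positive lag offset added to SC-like neurons.
#' @param base_rate baseline firing rate, spikes/s.
#' @param lag_range two-element lag range, ms; negative lags mean neural
#'   activity leads the kinematics (motor convention).
#' @param seed integer master seed; fans out to per-trial and per-neuron
#'   substreams so subsets are reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_trials = 28,
                              trial_duration_range = c(6, 10),
                              frame_rate = 200,
                              bin_width_ms = 5,
                              chew_frequency = 1.5,
                              chew_jitter = 0.08,
                              deformation_amplitudes = c(
                                flexion = 18, roll = 12, protrusion = 5,
                                length = 2, width = 1.5, swallow = 3),
                              swallow_rate = 1.5,
                              jaw_pitch_amplitude = 18,
                              neuron_counts = c(M1 = 100, SC = 55),
                              tuning_snr = 1.5,
                              sc_snr_factor = 0.35,
                              sc_lag_offset_ms = 50,
                              base_rate = 10,
                              lag_range = c(-120, -20),
                              seed = 1L) {
  # tolerate YAML-sourced configs, where vectors arrive as lists
  if (is.list(deformation_amplitudes))
    deformation_amplitudes <- unlist(deformation_amplitudes)
  if (is.list(neuron_counts)) neuron_counts <- unlist(neuron_counts)
  if (is.list(trial_duration_range))
    trial_duration_range <- unlist(trial_duration_range)
  if (is.list(lag_range)) lag_range <- unlist(lag_range)
  amp_names <- c("flexion", "roll", "protrusion", "length", "width", "swallow")
  amps <- deformation_amplitudes
  missing_amp <- setdiff(amp_names, names(amps))
  amps[missing_amp] <- 0
  amps <- amps[amp_names]
  if (any(amps < 0)) stop("deformation amplitudes must be non-negative")
  if (frame_rate * bin_width_ms != 1000)
    stop(sprintf(paste("frame_rate (%g Hz) must tie exactly to the %g ms",
                       "spike bins: frame_rate * bin_width_ms must be 1000"),
                 frame_rate, bin_width_ms))
  if (n_trials < 7)
    stop("n_trials must be at least the 7 cross-validation folds")
  if (base_rate <= 0) stop("base_rate must be positive (spikes/s)")
  stopifnot(length(trial_duration_range) == 2,
            trial_duration_range[1] <= trial_duration_range[2],
            trial_duration_range[1] > 0,
            tuning_snr >= 0, sc_snr_factor >= 0)
  structure(list(
    n_trials = as.integer(n_trials),
    trial_duration_range = trial_duration_range,
    frame_rate = frame_rate,
    bin_width_ms = bin_width_ms,
    chew_frequency = chew_frequency,
    chew_jitter = chew_jitter,
    deformation_amplitudes = amps,
    swallow_rate = swallow_rate,
    jaw_pitch_amplitude = jaw_pitch_amplitude,
    neuron_counts = neuron_counts,
    tuning_snr = tuning_snr,
    sc_snr_factor = sc_snr_factor,
    sc_lag_offset_ms = sc_lag_offset_ms,
    base_rate = base_rate,
    lag_range = lag_range,
    seed = as.integer(seed)), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d trials of %g-%g s @ %g Hz, seed %d\n",
              x$n_trials, x$trial_duration_range[1], x$trial_duration_range[2],
              x$frame_rate, x$seed))
  cat(sprintf("  chewing %g Hz; amplitudes: %s\n", x$chew_frequency,
              paste(names(x$deformation_amplitudes),
                    signif(x$deformation_amplitudes, 3),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  neurons: %s; tuning_snr %g, base rate %g sp/s\n",
              paste(names(x$neuron_counts), x$neuron_counts,
                    sep = "=", collapse = ", "),
              x$tuning_snr, x$base_rate))
  invisible(x)
}

# Slowly varying, C1-smooth unit-mean modulation: sum of low-frequency
# sinusoids with random phases.
slow_modulation <- function(t, depth = 0.15) {
  f <- stats::runif(3, 0.05, 0.3)
  ph <- stats::runif(3, 0, 2 * pi)
  s <- rowSums(sapply(1:3, function(k) sin(2 * pi * f[k] * t + ph[k]))) / 3
  1 + depth * s
}

# Latent mode time-courses for one trial. All modes share the chew phase;
# the onset/offset envelope brings the tongue to rest at both trial edges
# so frame 1 sits at the rest posture.
simulate_trial_latents <- function(config, duration) {
  fr <- config$frame_rate
  nf <- round(duration * fr)
  t <- (seq_len(nf) - 1) / fr
  amps <- config$deformation_amplitudes

  # chew phase with slowly drifting instantaneous frequency
  f_inst <- config$chew_frequency * slow_modulation(t, config$chew_jitter)
  phase <- 2 * pi * cumsum(f_inst) / fr

  ramp <- 0.7  # s, raised-cosine onset/offset
  env <- pmin(1, pmin(t, max(t) - t) / ramp)
  env <- 0.5 - 0.5 * cos(pi * pmin(env, 1))

  mode <- function(amp, phase_off, depth = 0.15) {
    m <- env * slow_modulation(t, depth)
    m <- m / max(m)
    amp * m * sin(phase + phase_off)
  }
  latents <- data.frame(
    time_s = t,
    phase = phase,
    flexion    = mode(amps["flexion"],    stats::runif(1, 0, 2 * pi)),
    roll       = mode(amps["roll"],       stats::runif(1, 0, 2 * pi)),
    protrusion = mode(amps["protrusion"], stats::runif(1, 0, 2 * pi)),
    length     = mode(amps["length"],     stats::runif(1, 0, 2 * pi)),
    width      = mode(amps["width"],      stats::runif(1, 0, 2 * pi)))

  # swallow-like transients: raised cosine bumps, away from trial edges
  swallow <- numeric(nf)
  n_sw <- if (amps["swallow"] > 0) stats::rpois(1, config$swallow_rate) else 0L
  sw_times <- if (n_sw > 0 && duration > 3)
    stats::runif(n_sw, 1.2, duration - 1.2) else numeric(0)
  half <- 0.35  # s, half-width of the transient
  for (ts in sw_times) {
    idx <- which(abs(t - ts) < half)
    swallow[idx] <- swallow[idx] +
      amps["swallow"] * 0.5 * (1 + cos(pi * (t[idx] - ts) / half))
  }
  latents$swallow <- swallow

  # gape-cycle labels: one per frame
  cycle <- floor(phase / (2 * pi))
  label <- rep("chew", nf)
  label[cycle <= 0] <- "stage1_transport"
  label[cycle >= max(cycle)] <- "stage2_transport"
  label[swallow > 0.05 * max(amps["swallow"], 1e-12)] <- "swallow"
  latents$label <- label
  latents
}

# Apply the latent modes of one frame to the rest constellation.
deform_constellation <- function(rest, flexion, roll, protrusion,
                                 len, wid, swallow) {
  P <- rest
  cx <- mean(rest[, "X"])
  # regional scaling: length along X, width along Z, about the centroid
  P[, "X"] <- cx + (P[, "X"] - cx) * (1 + len / 30)
  P[, "Z"] <- P[, "Z"] * (1 + wid / 10)
  # sagittal bending: rotate markers anterior of the middle-superficial
  # midpoint about a mediolateral (Z) axis through that midpoint
  vertex <- colMeans(P[c("middle_superficial_R", "middle_superficial_L"), ])
  ant <- c("tip", "anterior_superficial_R", "anterior_superficial_L",
           "anterior_deep")
  Rz <- rot_z(-deg2rad(flexion))
  P[ant, ] <- sweep(sweep(P[ant, ], 2, vertex) %*% t(Rz), 2, vertex, "+")
  # swallow transient: posterior elevation
  P["posterior_deep", "Y"] <- P["posterior_deep", "Y"] + swallow
  P[c("middle_superficial_R", "middle_superficial_L"), "Y"] <-
    P[c("middle_superficial_R", "middle_superficial_L"), "Y"] + 0.5 * swallow
  # axial roll: rigid rotation about an anteroposterior axis through the
  # rest centroid (leaves X coordinates unchanged)
  ctr <- colMeans(rest)
  Rx <- rot_x(deg2rad(roll))
  P <- sweep(sweep(P, 2, ctr) %*% t(Rx), 2, ctr, "+")
  dimnames(P) <- dimnames(rest)
  # anteroposterior translation
  P[, "X"] <- P[, "X"] + protrusion
  P
}

#' Simulate marker kinematics for a feeding session
#'
#' Generates, per trial, the 7-marker tongue trajectories, cranium and
#' mandible rigid-body transform series, and the ground-truth latent
#' mode traces and gape-cycle labels. Trajectories are C1-smooth,
#' trial durations are drawn uniformly from the configured range, and
#' everything is reproducible from the config seed.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `markers`, `cranium`, `mandible` (lists,
#'   one element per trial), `ground_truth` (per-trial latents and
#'   labels), and `config`.
#' @export
simulate_kinematics <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rest <- rest_constellation()
  fr <- config$frame_rate
  durations <- with_seed(substream_seed(config$seed, 1, 0),
    stats::runif(config$n_trials, config$trial_duration_range[1],
                 config$trial_duration_range[2]))
  condyle <- rbind(c(-35, 8, -12), c(-35, 8, 12))
  c_mid <- colMeans(condyle)

  markers <- list(); cranium <- list(); mandible <- list(); truth <- list()
  for (tr in seq_len(config$n_trials)) {
    lat <- with_seed(substream_seed(config$seed, 2, tr),
                     simulate_trial_latents(config, durations[tr]))
    nf <- nrow(lat)
    pos <- array(NA_real_, c(nf, 3, 7))
    for (i in seq_len(nf)) {
      pos[i, , ] <- t(deform_constellation(
        rest, lat$flexion[i], lat$roll[i], lat$protrusion[i],
        lat$length[i], lat$width[i], lat$swallow[i]))
    }
    # degenerate-geometry guard: markers must not cross
    mind <- min(apply(pos, 1, function(p) min(stats::dist(t(matrix(p, 3)))) ))
    if (mind < 1)
      stop(sprintf(paste("deformation amplitudes too large: markers approach",
                         "within %.2f mm (< 1 mm) in trial %d;",
                         "reduce deformation_amplitudes"), mind, tr))
    markers[[tr]] <- marker_trajectories(pos, rownames(rest),
                                         frame_rate = fr, trial = tr)

    # mandible pitch: opens once per chew cycle, phase-locked to the
    # (jittered) chew phase, rotating about the condylar axis
    pitch <- -deg2rad(config$jaw_pitch_amplitude) *
      (0.5 - 0.5 * cos(lat$phase))
    man <- array(0, c(4, 4, nf)); cra <- array(0, c(4, 4, nf))
    for (i in seq_len(nf)) {
      R <- rot_axis(c(0, 0, 1), pitch[i])
      man[, , i] <- homog(R, c_mid - R %*% c_mid)
      cra[, , i] <- diag(4)
    }
    mandible[[tr]] <- rigid_transforms(man, "mandible", fr, trial = tr)
    cranium[[tr]] <- rigid_transforms(cra, "cranium", fr, trial = tr)
    lat$jaw_pitch <- rad2deg(pitch)
    truth[[tr]] <- lat
  }
  list(markers = markers, cranium = cranium, mandible = mandible,
       ground_truth = list(latents = truth, rest = rest, condyle = condyle),
       config = config)
}

#' Simulate lag-tuned Poisson spiking populations
#'
#' Encoding model: for neuron *i* with tuning weights `w` over the
#' z-scored kinematic variables `z(t)` and lag `L`,
#' `rate(t) = softplus(b + g * sum_v w_v z_v(t - L))` with `b` chosen so a
#' flat input gives `base_rate`, and `g = tuning_snr` (times
#' `sc_snr_factor` for the SC-like population, which also receives a
#' positive `sc_lag_offset_ms`). Spikes are drawn as an inhomogeneous
#' Poisson process at the frame resolution.
#'
#' @param kinematics list of per-trial kinematic variable data frames (as
#'   returned by [compute_standard_variables()], or any numeric frame of
#'   per-frame variables with a `time_s` column).
#' @param config a [simulation_config()].
#' @return A list: `spikes` (a [spike_events()] table), `neurons`
#'   (metadata: id, region, lag_ms, tuning gain), `tuning` (weight matrix,
#'   one row per neuron).
#' @export
simulate_neurons <- function(kinematics, config) {
  stopifnot(inherits(config, "simulation_config"))
  fr <- config$frame_rate
  dt <- 1 / fr
  var_cols <- setdiff(names(kinematics[[1]]),
                      c("time_s", "trial", "frame", "label"))
  all_mat <- do.call(rbind, lapply(kinematics, function(k)
    as.matrix(k[var_cols])))
  mu <- colMeans(all_mat)
  sg <- apply(all_mat, 2, stats::sd)
  sg[sg < 1e-12] <- 1

  counts <- config$neuron_counts
  regions <- rep(names(counts), counts)
  n_neurons <- length(regions)
  ids <- sprintf("%s_%03d", regions, unlist(lapply(counts, seq_len)))

  # per-neuron tuning from seeded substreams
  W <- matrix(0, n_neurons, length(var_cols),
              dimnames = list(ids, var_cols))
  lag_ms <- numeric(n_neurons); gain <- numeric(n_neurons)
  for (i in seq_len(n_neurons)) {
    prm <- with_seed(substream_seed(config$seed, 3, i), {
      w <- stats::rnorm(length(var_cols))
      list(w = w / sqrt(sum(w^2)),
           lag = stats::runif(1, config$lag_range[1], config$lag_range[2]))
    })
    W[i, ] <- prm$w
    sc <- regions[i] == "SC"
    lag_ms[i] <- prm$lag + if (sc) config$sc_lag_offset_ms else 0
    gain[i] <- config$tuning_snr * if (sc) config$sc_snr_factor else 1
  }
  b <- softplus_inv(config$base_rate)

  ev <- vector("list", length(kinematics) * n_neurons)
  k <- 0
  for (tr in seq_along(kinematics)) {
    Z <- sweep(sweep(as.matrix(kinematics[[tr]][var_cols]), 2, mu), 2, sg, "/")
    nf <- nrow(Z)
    drive <- Z %*% t(W)  # frames x neurons, before lag shift
    for (i in seq_len(n_neurons)) {
      shift <- round(lag_ms[i] / 1000 * fr)  # frames; rate(t) uses z(t - shift)
      idx <- pmin(pmax(seq_len(nf) - shift, 1L), nf)
      rate <- softplus(b + gain[i] * drive[idx, i])
      times <- with_seed(substream_seed(config$seed, 4, tr * 100000 + i), {
        n_sp <- stats::rpois(nf, rate * dt)
        tot <- sum(n_sp)
        if (tot == 0) numeric(0)
        else sort(rep((which(n_sp > 0) - 1) * dt, n_sp[n_sp > 0]) +
                    stats::runif(tot, 0, dt))
      })
      if (length(times)) {
        k <- k + 1
        ev[[k]] <- data.frame(trial = tr, neuron_id = ids[i],
                              region = regions[i], spike_time_s = times)
      }
    }
  }
  spikes <- spike_events(do.call(rbind, ev[seq_len(k)]))
  list(spikes = spikes,
       neurons = data.frame(neuron_id = ids, region = regions,
                            lag_ms = lag_ms, gain = gain,
                            stringsAsFactors = FALSE),
       tuning = W)
}

#' Build a complete synthetic feeding dataset
#'
#' Runs [simulate_kinematics()], derives the standard kinematic variables,
#' and simulates the spiking populations; optionally writes all artifacts
#' to `dir` in the package's CSV formats.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, landmark, transform
#'   and spike CSVs plus the config are written there.
#' @return An object of class `feeding_dataset`: config, per-trial
#'   markers/transforms, kinematic variable tables, spikes, neuron
#'   metadata, ground truth.
#' @export
make_dataset <- function(config = simulation_config(), dir = NULL) {
  sim <- simulate_kinematics(config)
  kin <- lapply(seq_along(sim$markers), function(tr)
    compute_standard_variables(sim$markers[[tr]], sim$mandible[[tr]],
                               sim$cranium[[tr]],
                               reference = sim$ground_truth$rest,
                               condyle_axis = sim$ground_truth$condyle))
  neur <- simulate_neurons(kin, config)
  ds <- structure(list(
    config = config, markers = sim$markers, cranium = sim$cranium,
    mandible = sim$mandible, kinematics = kin, spikes = neur$spikes,
    neurons = neur$neurons, tuning = neur$tuning,
    ground_truth = sim$ground_truth), class = "feeding_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.feeding_dataset <- function(x, ...) {
  cat(sprintf("Synthetic feeding dataset: %d trials @ %g Hz, %d neurons (%s)\n",
              length(x$markers), x$config$frame_rate, nrow(x$neurons),
              paste(names(x$config$neuron_counts), x$config$neuron_counts,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  total frames %d, total spikes %d\n",
              sum(vapply(x$markers, n_frames, 1L)), nrow(x$spikes)))
  invisible(x)
}

#' Trial durations of a dataset, seconds
#' @param dataset a `feeding_dataset`.
#' @return Numeric vector of per-trial durations.
#' @export
trial_durations <- function(dataset) {
  vapply(dataset$markers, function(m) n_frames(m) / m$frame_rate, numeric(1))
}

#' Write a feeding dataset to a directory
#' @param dataset a `feeding_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmarks(dataset$markers, file.path(dir, "landmarks.csv"))
  write_transforms(c(dataset$cranium, dataset$mandible),
                   file.path(dir, "transforms.csv"))
  write_spikes(dataset$spikes, file.path(dir, "spikes.csv"))
  utils::write.csv(dataset$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE, quote = FALSE)
  kin <- do.call(rbind, lapply(seq_along(dataset$kinematics), function(tr)
    cbind(trial = tr, dataset$kinematics[[tr]])))
  utils::write.csv(kin, file.path(dir, "kinematics.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- dataset$config
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.numeric(v)) as.list(v) else v), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a feeding dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @return A `feeding_dataset` (ground truth is not persisted; the
#'   kinematic tables are read back as written).
#' @export
read_dataset <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg_raw <- lapply(cfg_raw, function(v)
    if (is.list(v)) unlist(v) else v)
  config <- do.call(simulation_config, cfg_raw)
  marks <- read_landmarks(file.path(dir, "landmarks.csv"),
                          frame_rate = config$frame_rate)
  tfs <- read_transforms(file.path(dir, "transforms.csv"),
                         frame_rate = config$frame_rate)
  kin_tab <- utils::read.csv(file.path(dir, "kinematics.csv"))
  kin <- lapply(split(kin_tab, kin_tab$trial), function(d) {
    d$trial <- NULL; rownames(d) <- NULL; d
  })
  structure(list(
    config = config,
    markers = unname(marks),
    cranium = unname(lapply(tfs, `[[`, "cranium")),
    mandible = unname(lapply(tfs, `[[`, "mandible")),
    kinematics = unname(kin),
    spikes = read_spikes(file.path(dir, "spikes.csv")),
    neurons = utils::read.csv(file.path(dir, "neurons.csv"),
                              stringsAsFactors = FALSE),
    ground_truth = NULL), class = "feeding_dataset")
}
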