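# File formats: landmark CSV, transform CSV, spike-event CSV, run config.
#
# All tables are plain CSV so artifacts stay inspectable. Numeric columns
# are written with 12 significant digits, which makes write -> read round
# trips lossless well below the 1e-9 mm contract.

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write marker trajectories to a landmark CSV
#'
#' Columns: `trial`, `frame` (0-based, contiguous), `time_s`
#' (= frame / frame_rate), then `<marker>_X`, `<marker>_Y`, `<marker>_Z`
#' per marker, in mm.
#'
#' @param x a `marker_trajectories` object or a list of them (one per trial).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path) {
  trials <- if (inherits(x, "marker_trajectories")) list(x) else x
  rows <- lapply(trials, function(tr) {
    nf <- n_frames(tr)
    df <- data.frame(trial = rep(tr$trial, nf), frame = seq_len(nf) - 1L,
                     time_s = fmt_num((seq_len(nf) - 1) / tr$frame_rate))
    for (m in tr$markers) {
      xyz <- marker_xyz(tr, m)
      df[[paste0(m, "_X")]] <- fmt_num(xyz[, 1])
      df[[paste0(m, "_Y")]] <- fmt_num(xyz[, 2])
      df[[paste0(m, "_Z")]] <- fmt_num(xyz[, 3])
    }
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landmark CSV
#'
#' @param path landmark CSV file (see [write_landmarks()] for the dialect).
#' @param frame_rate sampling rate in Hz used to check `time_s`; inferred
#'   from the time column when `NULL`.
#' @return A named list of `marker_trajectories`, one element per trial.
#' @export
read_landmarks <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("trial", "frame", "time_s")
  if (!all(need %in% names(df)))
    stop("landmark CSV must start with columns: ", paste(need, collapse = ", "))
  coord_cols <- grep("_(X|Y|Z)$", names(df), value = TRUE)
  markers <- unique(sub("_(X|Y|Z)$", "", coord_cols))
  if (any(!is.finite(as.matrix(df[coord_cols])))) {
    bad <- which(!stats::complete.cases(df[coord_cols]))[1]
    stop(sprintf("non-finite coordinate at row %d of %s", bad, path))
  }
  out <- list()
  for (tr in unique(df$trial)) {
    sub <- df[df$trial == tr, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (!identical(as.integer(sub$frame), seq_len(nrow(sub)) - 1L)) {
      gap <- which(diff(sub$frame) != 1)[1]
      stop(sprintf("non-contiguous frame index in trial %s near frame %s",
                   tr, sub$frame[gap]))
    }
    fr <- frame_rate %||%
      (if (nrow(sub) > 1) round(1 / stats::median(diff(sub$time_s))) else 200)
    pos <- array(NA_real_, c(nrow(sub), 3, length(markers)))
    for (j in seq_along(markers)) {
      m <- markers[j]
      pos[, , j] <- as.matrix(sub[paste0(m, c("_X", "_Y", "_Z"))])
    }
    out[[as.character(tr)]] <-
      marker_trajectories(pos, markers, frame_rate = fr, trial = tr)
  }
  out
}

#' Write rigid-body transforms to a transform CSV
#'
#' Columns: `trial`, `frame`, `body`, row-major rotation entries
#' `r11..r33`, translation `tx,ty,tz` (mm).
#'
#' @param x a `rigid_transforms` object or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(x, path) {
  series <- if (inherits(x, "rigid_transforms")) list(x) else x
  rows <- lapply(series, function(tr) {
    nf <- n_frames(tr)
    flat <- t(vapply(seq_len(nf), function(i) {
      m <- tr$transforms[, , i]
      c(t(m[1:3, 1:3]), m[1:3, 4])
    }, numeric(12)))
    colnames(flat) <- c("r11", "r12", "r13", "r21", "r22", "r23",
                        "r31", "r32", "r33", "tx", "ty", "tz")
    df <- data.frame(trial = rep(tr$trial, nf), frame = seq_len(nf) - 1L,
                     body = tr$body)
    for (cn in colnames(flat)) df[[cn]] <- fmt_num(flat[, cn])
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transform CSV
#'
#' @param path transform CSV (see [write_transforms()]).
#' @param frame_rate Hz; default 200.
#' @return Nested list: `out[[trial]][[body]]` is a `rigid_transforms`.
#' @export
read_transforms <- function(path, frame_rate = 200) {
  df <- utils::read.csv(path, check.names = FALSE)
  rot_cols <- c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33")
  need <- c("trial", "frame", "body", rot_cols, "tx", "ty", "tz")
  if (!all(need %in% names(df)))
    stop("transform CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (tr in unique(df$trial)) {
    out[[as.character(tr)]] <- list()
    for (body in unique(df$body[df$trial == tr])) {
      sub <- df[df$trial == tr & df$body == body, , drop = FALSE]
      sub <- sub[order(sub$frame), , drop = FALSE]
      arr <- array(0, c(4, 4, nrow(sub)))
      for (i in seq_len(nrow(sub))) {
        R <- matrix(as.numeric(sub[i, rot_cols]), 3, 3, byrow = TRUE)
        arr[, , i] <- homog(R, as.numeric(sub[i, c("tx", "ty", "tz")]))
      }
      out[[as.character(tr)]][[body]] <-
        rigid_transforms(arr, body, frame_rate = frame_rate, trial = tr)
    }
  }
  out
}

#' Write spike events to CSV
#'
#' Columns: `trial`, `neuron_id`, `region` (M1 | SC), `spike_time_s`
#' (seconds from trial start).
#'
#' @param x a `spike_events` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(x, path) {
  df <- as.data.frame(x)
  df$spike_time_s <- fmt_num(df$spike_time_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike-event CSV
#' @param path spike-event CSV (see [write_spikes()]).
#' @return A `spike_events` data.frame.
#' @export
read_spikes <- function(path) {
  spike_events(utils::read.csv(path))
}

#' Read a structured run configuration (YAML)
#'
#' Nested key/value config; the `simulation` block is passed to
#' [simulation_config()].
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
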