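# Core data containers for the pipeline.
#
# A trial's landmark data is a `marker_trajectories` object: an
# (n_frames x 3 x n_markers) array of positions in the cranial frame (mm),
# with axes X = anteroposterior (positive anterior), Y = superoinferior
# (positive superior), Z = mediolateral. Rigid bodies (cranium, mandible)
# are `rigid_transforms`: a 4 x 4 x n_frames array of homogeneous
# transforms. Spikes are event tables (trial, neuron_id, region,
# spike_time_s).

#' Canonical tongue marker names
#'
#' The seven-marker constellation, in the numbering used for the regional
#' length/width pairs: 1 tip, 2/3 anterior superficial right/left,
#' 4 anterior deep, 5/6 middle superficial right/left, 7 posterior deep.
#'
#' @return Character vector of the 7 marker names, in canonical order.
#' @export
tongue_markers <- function() {
  c("tip",
    "anterior_superficial_R", "anterior_superficial_L",
    "anterior_deep",
    "middle_superficial_R", "middle_superficial_L",
    "posterior_deep")
}

#' Construct a marker trajectory set
#'
#' @param positions numeric array, `n_frames x 3 x n_markers`, mm in the
#'   cranial frame; axis order X (anteroposterior, positive anterior),
#'   Y (superoinferior), Z (mediolateral).
#' @param markers character vector of marker names (third dimension).
#' @param frame_rate sampling rate in Hz.
#' @param trial trial identifier.
#' @return An object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(positions, markers = tongue_markers(),
                                frame_rate = 200, trial = 1L) {
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[2] == 3, dim(positions)[3] == length(markers))
  if (!all(is.finite(positions)))
    stop("marker positions must be finite; found non-finite coordinates")
  dimnames(positions) <- list(NULL, c("X", "Y", "Z"), markers)
  structure(list(positions = positions, markers = markers,
                 frame_rate = frame_rate, trial = trial),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("Marker trajectories: trial %s, %d frames @ %g Hz, %d markers\n",
              x$trial, n_frames(x), x$frame_rate, length(x$markers)))
  invisible(x)
}

n_frames <- function(x) UseMethod("n_frames")
#' @export
n_frames.marker_trajectories <- function(x) dim(x$positions)[1]
#' @export
n_frames.rigid_transforms <- function(x) dim(x$transforms)[3]

# Positions of one marker as an n x 3 matrix (even for n = 1).
marker_xyz <- function(x, name) {
  if (!name %in% x$markers)
    stop(sprintf("unknown marker name '%s' (have: %s)",
                 name, paste(x$markers, collapse = ", ")))
  matrix(x$positions[, , name], ncol = 3)
}

#' Construct a rigid-body transform series
#'
#' @param transforms numeric array `4 x 4 x n_frames` of homogeneous
#'   transforms mapping body-fixed coordinates into the world frame.
#' @param body body name, `"cranium"` or `"mandible"`.
#' @param frame_rate sampling rate, Hz.
#' @param trial trial identifier.
#' @param tol orthonormality tolerance for the rotation blocks.
#' @return An object of class `rigid_transforms`.
#' @export
rigid_transforms <- function(transforms, body, frame_rate = 200, trial = 1L,
                             tol = 1e-6) {
  stopifnot(is.array(transforms), length(dim(transforms)) == 3,
            all(dim(transforms)[1:2] == 4))
  for (i in seq_len(dim(transforms)[3])) {
    R <- transforms[1:3, 1:3, i]
    if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
      stop(sprintf("rotation block at frame %d is not a proper rotation (tol %g)",
                   i, tol))
  }
  structure(list(transforms = transforms, body = body,
                 frame_rate = frame_rate, trial = trial),
            class = "rigid_transforms")
}

#' @export
print.rigid_transforms <- function(x, ...) {
  cat(sprintf("Rigid transforms: body '%s', trial %s, %d frames @ %g Hz\n",
              x$body, x$trial, n_frames(x), x$frame_rate))
  invisible(x)
}

#' Construct a spike event table
#'
#' @param trial,neuron_id,region,spike_time_s vectors of equal length (or
#'   a data.frame with those columns as the first argument).
#' @return A data.frame of class `spike_events` sorted by trial, neuron,
#'   time.
#' @export
spike_events <- function(trial, neuron_id = NULL, region = NULL,
                         spike_time_s = NULL) {
  if (is.data.frame(trial)) {
    df <- trial
    need <- c("trial", "neuron_id", "region", "spike_time_s")
    if (!all(need %in% names(df)))
      stop("spike event table must have columns: ", paste(need, collapse = ", "))
    df <- df[need]
  } else {
    df <- data.frame(trial = trial, neuron_id = neuron_id,
                     region = region, spike_time_s = spike_time_s)
  }
  if (any(df$spike_time_s < 0))
    stop("spike times must be non-negative (seconds from trial start)")
  df <- df[order(df$trial, df$neuron_id, df$spike_time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_events", "data.frame")
  df
}
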