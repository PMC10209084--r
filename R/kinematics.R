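# Standard tongue kinematic variables and jaw pitch.
#
# Variables (per frame): sagittal flexion (deg, angle at the middle
# superficial vertex between the posterior deep marker and the tip),
# protrusion (mm, mean anteroposterior position of the three anterior-most
# markers), roll (deg, pseudo-rigid-body fit of a rest constellation to
# the anterior 6 markers, intrinsic X-Y-Z Tait-Bryan decomposition, X
# component), two regional lengths and two widths (mm, straight-line
# marker pair distances), and jaw pitch (deg, rotation of the
# mandible-relative-to-cranium transform about the inter-condylar axis).

#' Zero-lag low-pass Butterworth filter
#'
#' Second-order Butterworth applied forward and backward (fourth-order
#' effective magnitude response, zero phase lag), with odd reflection
#' padding at the edges.
#'
#' @param series numeric vector (one per-frame signal).
#' @param cutoff cutoff frequency, Hz (default 30).
#' @param frame_rate sampling rate, Hz.
#' @param order filter order before the forward-backward pass.
#' @return Filtered series, same length as the input.
#' @export
lowpass_filter <- function(series, cutoff = 30, frame_rate = 200, order = 2) {
  stopifnot(frame_rate > 2 * cutoff)
  n <- length(series)
  if (n < 3 * (order + 1))
    stop(sprintf("series too short to filter: %d samples < 3 x (order+1) = %d",
                 n, 3 * (order + 1)))
  bf <- signal::butter(order, cutoff / (frame_rate / 2), type = "low")
  pad <- min(n - 1, max(3 * (order + 1), round(frame_rate / cutoff) * 6))
  # filter deviations from the mean (exact DC passthrough) with an odd
  # (point-reflected) extension to damp the IIR edge transients
  m <- mean(series)
  x <- series - m
  pre <- 2 * x[1] - rev(x[2:(pad + 1)])
  post <- 2 * x[n] - rev(x[(n - pad):(n - 1)])
  ext <- c(pre, x, post)
  fwd <- signal::filter(bf, ext)
  bwd <- rev(as.numeric(signal::filter(bf, rev(as.numeric(fwd)))))
  bwd[(pad + 1):(pad + n)] + m
}

#' Jaw pitch about the inter-condylar axis
#'
#' Computes the mandible-relative-to-cranium transform per frame
#' (mandible transform pre-multiplied by the inverse cranium transform)
#' and extracts the rotation about the axis through both mandibular
#' condyles — the primary axis of a temporomandibular joint coordinate
#' system. Zero at the reference posture; additive for composed rotations
#' about the axis.
#'
#' @param mandible,cranium `rigid_transforms` with equal frame counts.
#' @param condyle_axis 2 x 3 matrix: the two condyle points (cranial
#'   frame, mm).
#' @return Numeric vector of pitch angles, degrees.
#' @export
jaw_pitch <- function(mandible, cranium, condyle_axis) {
  stopifnot(inherits(mandible, "rigid_transforms"),
            inherits(cranium, "rigid_transforms"),
            n_frames(mandible) == n_frames(cranium))
  condyle_axis <- as.matrix(condyle_axis)
  stopifnot(all(dim(condyle_axis) == c(2, 3)))
  u <- condyle_axis[2, ] - condyle_axis[1, ]
  if (sqrt(sum(u^2)) < 1e-9) stop("condyle points must be distinct")
  u <- u / sqrt(sum(u^2))
  # v, w: orthonormal completion of the condylar axis
  v <- c(u[2], -u[1], 0)
  if (sum(v^2) < 1e-12) v <- c(1, 0, 0)
  v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nf <- n_frames(mandible)
  out <- numeric(nf)
  for (i in seq_len(nf)) {
    C <- cranium$transforms[, , i]
    if (abs(det(C[1:3, 1:3])) < 1e-9) stop("non-invertible cranium transform")
    rel <- solve(C) %*% mandible$transforms[, , i]
    Rv <- rel[1:3, 1:3] %*% v
    # angle of v's image in the plane orthogonal to the condylar axis
    out[i] <- atan2(sum(Rv * w), sum(Rv * v))
  }
  rad2deg(out)
}

#' Sagittal flexion angle
#'
#' Planar angle (degrees) at the middle superficial vertex between the
#' posterior deep marker and the tongue tip. With left/right middle
#' superficial markers, the vertex is their midpoint.
#'
#' @param markers a `marker_trajectories` containing `tip`,
#'   `posterior_deep` and the middle superficial marker(s).
#' @return Numeric vector, degrees, in (0, 180]; frames with a coincident
#'   marker yield `NA` and a warning naming the frame.
#' @export
sagittal_flexion <- function(markers) {
  tip <- marker_xyz(markers, "tip")
  post <- marker_xyz(markers, "posterior_deep")
  if (all(c("middle_superficial_R", "middle_superficial_L") %in%
            markers$markers)) {
    vertex <- (marker_xyz(markers, "middle_superficial_R") +
                 marker_xyz(markers, "middle_superficial_L")) / 2
  } else {
    vertex <- marker_xyz(markers, "middle_superficial")
  }
  a <- tip - vertex
  b <- post - vertex
  na_ <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  bad <- which(na_ < 1e-9 | nb < 1e-9)
  if (length(bad)) {
    warning("coincident markers; flexion undefined at frames: ",
            paste(utils::head(bad, 10), collapse = ", "))
  }
  cosang <- rowSums(a * b) / (na_ * nb)
  ang <- rad2deg(acos(pmin(1, pmax(-1, cosang))))
  ang[bad] <- NA_real_
  ang
}

#' Tongue protrusion
#'
#' Mean anteroposterior (X) position of the three anterior-most markers
#' (tip and the two anterior superficial markers), relative to the
#' cranium.
#'
#' @param markers a `marker_trajectories`.
#' @return Numeric vector, mm.
#' @export
protrusion <- function(markers) {
  need <- c("tip", "anterior_superficial_R", "anterior_superficial_L")
  missing_m <- setdiff(need, markers$markers)
  if (length(missing_m))
    stop("protrusion requires markers: ", paste(missing_m, collapse = ", "))
  (marker_xyz(markers, need[1])[, 1] +
     marker_xyz(markers, need[2])[, 1] +
     marker_xyz(markers, need[3])[, 1]) / 3
}

# Rigid (no scale, no reflection) least-squares fit of `ref` (n x 3) onto
# `pts` (n x 3); returns the rotation. Kabsch with determinant correction.
kabsch_rotation <- function(ref, pts) {
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(pts, 2, colMeans(pts))
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("rank-deficient marker configuration (collinear markers)")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)
}

# Intrinsic X-Y-Z Tait-Bryan decomposition; returns angles (rad) with
# R = Rx(a) %*% Ry(b) %*% Rz(c).
tait_bryan_xyz <- function(R) {
  b <- asin(pmin(1, pmax(-1, R[1, 3])))
  a <- atan2(-R[2, 3], R[3, 3])
  c <- atan2(-R[1, 2], R[1, 1])
  c(x = a, y = b, z = c)
}

#' Tongue roll by a pseudo-rigid-body fit
#'
#' Per frame, the rest constellation of the anterior 6 markers (all but
#' the posterior deep marker) is fitted to the observed markers by a
#' rigid rotation + translation (no scale, no reflection); the rotation
#' is decomposed into intrinsic X-Y-Z Tait-Bryan angles and the X
#' (anteroposterior-axis) angle is returned.
#'
#' @param markers a `marker_trajectories`.
#' @param reference rest constellation: a matrix with marker rownames (at
#'   least the anterior 6), mm.
#' @param axes 3 x 3 rotation giving the anatomical axes of the reference
#'   posture in world coordinates (columns: anteroposterior,
#'   superoinferior, mediolateral). Defaults to the world axes; pass the
#'   same rotation applied to a rigidly moved reference so roll stays
#'   frame-independent.
#' @return Numeric vector of roll angles, degrees.
#' @export
tongue_roll <- function(markers, reference, axes = diag(3)) {
  anterior <- setdiff(markers$markers, "posterior_deep")
  reference <- as.matrix(reference)
  if (!all(anterior %in% rownames(reference)))
    stop("reference must contain the anterior 6 markers: ",
         paste(anterior, collapse = ", "))
  stopifnot(is_rotation(axes, tol = 1e-6))
  ref <- reference[anterior, , drop = FALSE]
  nf <- n_frames(markers)
  out <- numeric(nf)
  for (i in seq_len(nf)) {
    pts <- t(matrix(markers$positions[i, , anterior], nrow = 3))
    R <- tryCatch(kabsch_rotation(ref, pts), error = function(e)
      stop(sprintf("roll fit failed at frame %d: %s", i, conditionMessage(e)),
           call. = FALSE))
    # express the fitted rotation in the reference's anatomical frame
    out[i] <- tait_bryan_xyz(t(axes) %*% R %*% axes)[["x"]]
  }
  rad2deg(out)
}

#' Straight-line marker pair distances
#'
#' Per-frame Euclidean distances of named marker pairs. The default pairs
#' are the regional length/width variables: anterior length (tip to
#' anterior deep), middle length (anterior deep to posterior deep),
#' anterior width (the two anterior superficial markers), middle width
#' (the two middle superficial markers).
#'
#' @param markers a `marker_trajectories`.
#' @param pairs named list of 2-element character vectors.
#' @return Data frame, one column per pair, mm.
#' @export
marker_distances <- function(markers, pairs = standard_pairs()) {
  out <- lapply(pairs, function(p) {
    stopifnot(length(p) == 2)
    a <- marker_xyz(markers, p[1])
    b <- marker_xyz(markers, p[2])
    sqrt(rowSums((a - b)^2))
  })
  as.data.frame(out)
}

#' Default regional length/width marker pairs
#' @return Named list of marker-name pairs.
#' @export
standard_pairs <- function() {
  list(anterior_length = c("tip", "anterior_deep"),
       middle_length = c("anterior_deep", "posterior_deep"),
       anterior_width = c("anterior_superficial_R", "anterior_superficial_L"),
       middle_width = c("middle_superficial_R", "middle_superficial_L"))
}

#' Names of the 7 standard tongue variables
#' @return Character vector.
#' @export
standard_variables <- function() {
  c("sagittal_flexion", "protrusion", "roll",
    "anterior_length", "middle_length", "anterior_width", "middle_width")
}

#' Compute the standard kinematic variable set for one trial
#'
#' Low-pass filters the marker coordinates and rigid-body transforms
#' (zero-lag Butterworth, default 30 Hz cutoff), then computes the 7
#' standard tongue variables plus jaw pitch on a shared time base.
#'
#' @param markers a `marker_trajectories`.
#' @param mandible,cranium `rigid_transforms` for the two bodies.
#' @param reference rest constellation for the roll fit; defaults to the
#'   first frame of the trial.
#' @param axes anatomical axes of the reference, passed to
#'   [tongue_roll()].
#' @param condyle_axis 2 x 3 matrix of condyle points for jaw pitch.
#' @param cutoff low-pass cutoff, Hz; `NULL` disables filtering.
#' @return A data.frame of class `kinematic_variables`: `time_s`, the 7
#'   tongue variables, `jaw_pitch`; attribute `frame_rate`.
#' @export
compute_standard_variables <- function(markers, mandible, cranium,
                                       reference = NULL, axes = diag(3),
                                       condyle_axis = rbind(c(-35, 8, -12),
                                                            c(-35, 8, 12)),
                                       cutoff = 30) {
  stopifnot(markers$frame_rate == mandible$frame_rate,
            markers$frame_rate == cranium$frame_rate)
  fr <- markers$frame_rate
  if (!is.null(cutoff)) {
    pos <- markers$positions
    for (m in seq_len(dim(pos)[3])) for (ax in 1:3)
      pos[, ax, m] <- lowpass_filter(pos[, ax, m], cutoff, fr)
    markers <- marker_trajectories(pos, markers$markers, fr, markers$trial)
  }
  if (is.null(reference)) reference <- t(markers$positions[1, , ])
  dists <- marker_distances(markers)
  out <- data.frame(
    time_s = (seq_len(n_frames(markers)) - 1) / fr,
    sagittal_flexion = sagittal_flexion(markers),
    protrusion = protrusion(markers),
    roll = tongue_roll(markers, reference, axes = axes),
    anterior_length = dists$anterior_length,
    middle_length = dists$middle_length,
    anterior_width = dists$anterior_width,
    middle_width = dists$middle_width,
    jaw_pitch = jaw_pitch(mandible, cranium, condyle_axis))
  attr(out, "frame_rate") <- fr
  class(out) <- c("kinematic_variables", "data.frame")
  out
}
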