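# Procrustes shape space over the tongue marker constellation.
#
# Each frame's 7 x 3 marker configuration is superimposed on a consensus
# posture by a constrained Procrustes fit (rotation + translation,
# optionally scale, never a reflection); PCA of the aligned, vectorized
# coordinates (21 dimensions) yields "complex deformation" variables:
# the shape PC scores.

#' Constrained Procrustes superimposition of two configurations
#'
#' Least-squares rigid (or similarity) fit of `source` onto `target`
#' with the rotation determinant forced to +1: reflections are never
#' returned, even when a reflected fit would have lower residual.
#'
#' @param source,target n x 3 landmark matrices (n >= 3, not collinear).
#' @param allow_scale fit a similarity transform (`TRUE`, default) or a
#'   strictly rigid one.
#' @return List: `rotation` (3 x 3, det +1), `translation`, `scale`,
#'   `residual` (RMS point distance after transform), and `fitted`
#'   (= scale * source %*% rotation + translation, row-wise).
#' @export
constrained_procrustes_fit <- function(source, target, allow_scale = TRUE) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) >= 3, all(dim(source) == dim(target)))
  mu_s <- colMeans(source); mu_t <- colMeans(target)
  A <- sweep(source, 2, mu_s); B <- sweep(target, 2, mu_t)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], .Machine$double.eps))
    stop("rank-deficient landmark configuration (collinear points)")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)  # maps centered source rows -> target rows
  s <- if (allow_scale) sum(sv$d * c(1, 1, d)) / sum(A^2) else 1
  t_vec <- mu_t - s * as.numeric(mu_s %*% R)
  fitted <- s * source %*% R + matrix(t_vec, nrow(source), 3, byrow = TRUE)
  list(rotation = R, translation = t_vec, scale = s,
       residual = sqrt(mean(rowSums((fitted - target)^2))),
       fitted = fitted)
}

centroid_size <- function(x) sqrt(sum(sweep(x, 2, colMeans(x))^2))

# Proper rotation taking a centered configuration onto its principal
# axes, with deterministic signs (largest-|coordinate| entry positive
# per axis; det forced to +1 on the minor axis).
canonical_rotation <- function(con) {
  V <- eigen(crossprod(con), symmetric = TRUE)$vectors
  for (j in 1:3) {
    cj <- con %*% V[, j]
    if (cj[which.max(abs(cj))] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Generalized Procrustes alignment of many configurations
#'
#' Iteratively superimposes every frame on the current consensus and
#' recomputes the consensus until it stabilises. The consensus is
#' centered and, with `allow_scale`, normalized to unit centroid size.
#' All trials are concatenated: one consensus per dataset.
#'
#' @param frames list of n x 3 matrices, or an `n_frames x 3 x n_markers`
#'   array.
#' @param allow_scale remove per-frame centroid size (default `TRUE`).
#' @param tol convergence tolerance on the consensus RMS change.
#' @param max_iter iteration cap; non-convergence warns and returns.
#' @return List of class `gpa_alignment`: `aligned` (list of aligned
#'   frames), `mean_shape`, `iterations`, `delta`, plus per-frame
#'   centering/scale bookkeeping (`centroids`, `sizes`).
#' @export
generalized_procrustes <- function(frames, allow_scale = TRUE,
                                   tol = 1e-10, max_iter = 100) {
  frames <- as_frame_list(frames)
  if (length(frames) < 2) stop("need at least 2 frames for GPA")
  centroids <- t(vapply(frames, colMeans, numeric(3)))
  sizes <- vapply(frames, centroid_size, numeric(1))
  if (any(sizes < 1e-12)) stop("degenerate (zero-size) frame in GPA input")
  pre <- lapply(seq_along(frames), function(i) {
    f <- sweep(frames[[i]], 2, centroids[i, ])
    if (allow_scale) f / sizes[i] else f
  })
  consensus <- pre[[1]]
  aligned <- pre
  it <- 0; delta <- Inf
  while (it < max_iter) {
    it <- it + 1
    aligned <- lapply(pre, function(f)
      constrained_procrustes_fit(f, consensus, allow_scale = FALSE)$fitted)
    new_con <- Reduce(`+`, aligned) / length(aligned)
    new_con <- sweep(new_con, 2, colMeans(new_con))
    if (allow_scale) new_con <- new_con / centroid_size(new_con)
    delta <- sqrt(mean((new_con - consensus)^2))
    consensus <- new_con
    if (delta < tol) break
  }
  if (delta >= tol)
    warning(sprintf("GPA did not converge in %d iterations (delta %.3g)",
                    max_iter, delta))
  # canonical orientation: consensus on its principal axes with
  # deterministic signs, so the alignment is invariant to rigid motion
  # of the raw input frames
  V <- canonical_rotation(consensus)
  consensus <- consensus %*% V
  aligned <- lapply(aligned, function(f) f %*% V)
  structure(list(aligned = aligned, mean_shape = consensus,
                 iterations = it, delta = delta,
                 centroids = centroids, sizes = sizes,
                 allow_scale = allow_scale),
            class = "gpa_alignment")
}

as_frame_list <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    if (dim(frames)[2] == 3) {
      # n_frames x 3 x n_markers
      lapply(seq_len(dim(frames)[1]), function(i) t(frames[i, , ]))
    } else stop("array input must be n_frames x 3 x n_markers")
  } else if (is.list(frames)) {
    lapply(frames, as.matrix)
  } else stop("frames must be a list of n x 3 matrices or a 3-d array")
}

# Collect all frames of a dataset's marker trajectories into one list.
dataset_frames <- function(dataset) {
  do.call(c, lapply(dataset$markers, function(m) as_frame_list(m$positions)))
}

#' Fit the Procrustes shape space (GPA + PCA)
#'
#' Runs [generalized_procrustes()] on all frames, flattens the aligned
#' configurations to 21-vectors (X, Y, Z per marker), column-mean-centers
#' them, and eigendecomposes their covariance. Component signs follow a
#' deterministic convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param frames list of 7 x 3 matrices, a 3-d positions array, or a
#'   `feeding_dataset` (all trials concatenated).
#' @param allow_scale passed to [generalized_procrustes()].
#' @param tol,max_iter GPA convergence controls.
#' @return An object of class `shape_space`: `mean_shape` (7 x 3),
#'   `basis` (21 x K orthonormal loadings), `eigenvalues`,
#'   `var_explained`, `scores` (training-frame scores), `gpa` bookkeeping.
#' @export
shape_pca <- function(frames, allow_scale = TRUE, tol = 1e-10,
                      max_iter = 100) {
  if (inherits(frames, "feeding_dataset")) frames <- dataset_frames(frames)
  frames <- as_frame_list(frames)
  if (length(frames) < 2) stop("need at least 2 frames for a shape PCA")
  p <- nrow(frames[[1]]) * 3
  if (length(frames) < p + 1)
    warning(sprintf("only %d frames for %d shape dimensions: rank-deficient PCA",
                    length(frames), p))
  gpa <- generalized_procrustes(frames, allow_scale = allow_scale,
                                tol = tol, max_iter = max_iter)
  X <- t(vapply(gpa$aligned, function(f) as.numeric(f), numeric(p)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  keep <- seq_len(min(p, nrow(Xc) - 1))
  basis <- eg$vectors[, keep, drop = FALSE]
  # deterministic sign: largest |loading| positive
  for (k in seq_len(ncol(basis))) {
    j <- which.max(abs(basis[, k]))
    if (basis[j, k] < 0) basis[, k] <- -basis[, k]
  }
  ev <- pmax(eg$values[keep], 0)
  marker_names <- rownames(frames[[1]]) %||% paste0("m", seq_len(p / 3))
  structure(list(
    mean_shape = matrix(ctr, ncol = 3,
                        dimnames = list(marker_names, c("X", "Y", "Z"))),
    basis = basis, eigenvalues = ev, var_explained = ev / sum(ev),
    scores = Xc %*% basis, center = ctr, gpa = gpa,
    n_frames = nrow(X)), class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("Procrustes shape space: %d frames, %d markers, %d components\n",
              x$n_frames, nrow(x$mean_shape), ncol(x$basis)))
  cum <- cumsum(x$var_explained)
  k90 <- which(cum >= 0.9)[1]
  cat(sprintf("  variance explained: PC1 %.1f%%, first 7 %.1f%%; %d PCs reach 90%%\n",
              100 * x$var_explained[1],
              100 * sum(x$var_explained[seq_len(min(7, length(cum)))]),
              k90))
  invisible(x)
}

#' @export
summary.shape_space <- function(object, k = 10, ...) {
  k <- min(k, length(object$eigenvalues))
  data.frame(component = seq_len(k),
             eigenvalue = object$eigenvalues[seq_len(k)],
             var_explained = object$var_explained[seq_len(k)],
             cumulative = cumsum(object$var_explained)[seq_len(k)])
}

#' @export
plot.shape_space <- function(x, k = 15, ...) {
  k <- min(k, length(x$var_explained))
  graphics::barplot(100 * x$var_explained[seq_len(k)],
                    names.arg = seq_len(k),
                    xlab = "shape component",
                    ylab = "% variance explained", ...)
  invisible(x)
}

#' Project frames into a fitted shape space
#'
#' Each frame is centered (and size-normalized if the space was fitted
#' with scaling), superimposed on the consensus, flattened, centered with
#' the training column means, and projected onto the first `k` basis
#' vectors.
#'
#' @param frames list / array of configurations, or a `feeding_dataset`.
#' @param space a fitted `shape_space`.
#' @param k number of components (default 7, the complex deformation
#'   variables).
#' @return Matrix of scores, frames x k, class `shape_scores`; attribute
#'   `var_explained` holds the per-component variance fractions.
#' @export
project_scores <- function(frames, space, k = 7) {
  stopifnot(inherits(space, "shape_space"))
  if (k > ncol(space$basis))
    stop(sprintf("k = %d exceeds the %d available components",
                 k, ncol(space$basis)))
  if (inherits(frames, "feeding_dataset")) frames <- dataset_frames(frames)
  frames <- as_frame_list(frames)
  X <- t(vapply(frames, function(f) {
    f <- sweep(f, 2, colMeans(f))
    if (space$gpa$allow_scale) f <- f / centroid_size(f)
    as.numeric(constrained_procrustes_fit(
      f, space$mean_shape, allow_scale = FALSE)$fitted)
  }, numeric(length(space$center))))
  sc <- sweep(X, 2, space$center) %*% space$basis[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("shape_pc", seq_len(k))
  structure(sc, var_explained = space$var_explained[seq_len(k)],
            class = c("shape_scores", class(sc)))
}

#' Reconstruct marker configurations from shape scores
#'
#' `mean_shape + basis %*% scores`, refolded to n x 3, in consensus
#' (shape-space) coordinates.
#'
#' @param scores frames x k score matrix from [project_scores()].
#' @param space the `shape_space` the scores came from.
#' @return List of n x 3 configurations, one per frame.
#' @export
reconstruct_shape <- function(scores, space) {
  stopifnot(inherits(space, "shape_space"))
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k > ncol(space$basis)) stop("score dimension exceeds basis size")
  flat <- sweep(scores %*% t(space$basis[, seq_len(k), drop = FALSE]),
                2, space$center, "+")
  nm <- rownames(space$mean_shape)
  lapply(seq_len(nrow(flat)), function(i)
    matrix(flat[i, ], ncol = 3, dimnames = list(nm, c("X", "Y", "Z"))))
}

#' Marker-wise reconstruction error
#'
#' Per-frame, per-marker Euclidean distance between reconstructed and
#' reference configurations.
#'
#' @param recon,truth lists of n x 3 configurations of equal length.
#' @return List: `per_frame` (frames x markers error matrix, mm), and
#'   `mean`, `median`, `max` across all entries.
#' @export
reconstruction_error <- function(recon, truth) {
  recon <- as_frame_list(recon); truth <- as_frame_list(truth)
  if (length(recon) != length(truth))
    stop("reconstruction and truth have different frame counts")
  per <- t(vapply(seq_along(recon), function(i)
    sqrt(rowSums((recon[[i]] - truth[[i]])^2)), numeric(nrow(recon[[1]]))))
  list(per_frame = per, mean = mean(per), median = stats::median(per),
       max = max(per))
}
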