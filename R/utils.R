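# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded substreams never perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Fan a base seed out into reproducible substream seeds (kept < 2^31).
substream_seed <- function(seed, stream, index) {
  (as.numeric(seed) * 48271 + stream * 9973 + index * 7919) %% 2147483629
}

softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  ifelse(x > 30, x, log1p(exp(x)))
}

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Elementary rotation matrices (right-handed, column-vector convention).
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Rotation about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# 4x4 homogeneous transform from rotation + translation.
homog <- function(R, t) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
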