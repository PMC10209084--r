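# Procrustes shape space: superimposition, GPA, shape PCA,
# projection and reconstruction.

rest <- tonguekin:::rest_constellation()

test_that("constrained Procrustes fit recovers constructed motions and never reflects", {
  # identity
  fit <- constrained_procrustes_fit(rest, rest)
  expect_equal_tol(fit$rotation, diag(3), 1e-12)
  expect_equal_tol(fit$translation, 0, 1e-12)
  expect_equal(fit$scale, 1, tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-12)
  # reflected target: best proper rotation returned, det always +1
  refl <- rest %*% diag(c(1, 1, -1))
  fit2 <- constrained_procrustes_fit(rest, refl)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  expect_gt(fit2$residual, 0.1)
  # random similarity motions reproduced to < 1e-9 residual
  set.seed(5)
  for (i in 1:20) {
    R <- random_rotation(); s <- stats::runif(1, 0.5, 2)
    tv <- stats::rnorm(3, sd = 10)
    target <- sweep(s * rest %*% t(R), 2, tv, "+")
    fit3 <- constrained_procrustes_fit(rest, target, allow_scale = TRUE)
    expect_lt(fit3$residual, 1e-9)
    expect_equal_tol(fit3$rotation, t(R), 1e-9)
    expect_equal(fit3$scale, s, tolerance = 1e-9)
    expect_equal(det(fit3$rotation), 1, tolerance = 1e-9)
  }
  # collinear input is rejected
  line <- cbind(1:7, 2 * (1:7), -1:5 * 0)
  expect_error(constrained_procrustes_fit(line, line), "rank-deficient")
})

make_shape_frames <- function(n = 60, seed = 9, deform = 0.5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f <- rest + deform * matrix(stats::rnorm(21), 7, 3)
    rownames(f) <- rownames(rest)
    f
  })
}

apply_rigid <- function(frames, seed = 1) {
  set.seed(seed)
  lapply(frames, function(f) {
    R <- random_rotation()
    out <- sweep(f %*% t(R), 2, stats::rnorm(3, sd = 20), "+")
    rownames(out) <- rownames(f)
    out
  })
}

test_that("GPA removes pure rigid/scale motion and is invariant to rigid pre-motion", {
  # frames that are all one shape under random similarity motions
  set.seed(2)
  frames <- lapply(1:25, function(i) {
    s <- stats::runif(1, 0.7, 1.4)
    f <- sweep(s * rest %*% t(random_rotation()), 2,
               stats::rnorm(3, sd = 15), "+")
    rownames(f) <- rownames(rest); f
  })
  gpa <- generalized_procrustes(frames)
  spread <- sapply(gpa$aligned, function(f) sqrt(mean((f - gpa$mean_shape)^2)))
  expect_lt(max(spread), 1e-8)
  # genuinely varying shapes: rigid pre-motion does not move the alignment
  frames2 <- make_shape_frames(30)
  g1 <- generalized_procrustes(frames2)
  g2 <- generalized_procrustes(apply_rigid(frames2, seed = 4))
  for (i in c(1, 15, 30))
    expect_equal_tol(g1$aligned[[i]], g2$aligned[[i]], 1e-7)
  # two distinct shapes with equal counts: consensus equals their
  # aligned average (closed-form two-shape GPA)
  a <- rest / tonguekin:::centroid_size(rest)
  b0 <- rest; b0["tip", 2] <- b0["tip", 2] + 4
  b0 <- sweep(b0, 2, colMeans(b0))
  b <- b0 / tonguekin:::centroid_size(b0)
  g3 <- generalized_procrustes(list(a, b, a, b), tol = 1e-14)
  con <- (g3$aligned[[1]] + g3$aligned[[2]]) / 2
  con <- sweep(con, 2, colMeans(con))
  con <- con / tonguekin:::centroid_size(con)
  expect_equal_tol(unname(g3$mean_shape), unname(con), 1e-7)
})

test_that("shape PCA: 21 input dimensions, deterministic signs, variance bookkeeping", {
  frames <- make_shape_frames(50)
  sp <- shape_pca(frames)
  expect_equal(nrow(sp$basis), 21)
  expect_equal(sum(sp$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(sp$eigenvalues) <= 1e-12))
  expect_equal_tol(crossprod(sp$basis), diag(ncol(sp$basis)), 1e-8)
  # the largest-magnitude loading of each component is positive
  for (k in seq_len(ncol(sp$basis)))
    expect_gt(sp$basis[which.max(abs(sp$basis[, k])), k], 0)
  # rank-2 construction: two orthogonal deformation modes hold the variance
  set.seed(21)
  m1 <- matrix(stats::rnorm(21), 7, 3); m1 <- m1 / sqrt(sum(m1^2))
  m2 <- matrix(stats::rnorm(21), 7, 3)
  m2 <- m2 - sum(m2 * m1) * m1; m2 <- m2 / sqrt(sum(m2^2))
  frames2 <- lapply(1:40, function(i) {
    f <- rest + 2 * sin(i) * m1 + 1.2 * cos(1.7 * i) * m2
    rownames(f) <- rownames(rest); f
  })
  sp2 <- shape_pca(frames2, allow_scale = FALSE)
  expect_gt(sum(sp2$var_explained[1:2]), 0.999)
  expect_error(shape_pca(frames[1]), "at least 2")
})

test_that("score projection is consistent with the training PCA", {
  frames <- make_shape_frames(40)
  sp <- shape_pca(frames)
  sc <- project_scores(frames, sp, k = 7)
  expect_equal_tol(unclass(sc), sp$scores[, 1:7], 1e-8)
  # training scores are centered per component
  expect_equal_tol(colMeans(sp$scores), 0, 1e-10)
  # the mean shape projects to the origin (exact up to the second-order
  # effect of unit-size normalisation: the mean of unit-size shapes has
  # centroid size slightly below 1)
  expect_equal_tol(project_scores(list(sp$mean_shape), sp, k = 7), 0, 1e-4)
  expect_error(project_scores(frames, sp, k = 50), "exceeds")
})

test_that("reconstruction: round trips, discarded-energy identity, monotone error", {
  frames <- make_shape_frames(45, deform = 0.4)
  sp <- shape_pca(frames)
  gpa_frames <- sp$gpa$aligned
  # zero scores reconstruct the mean shape exactly
  expect_equal_tol(reconstruct_shape(matrix(0, 1, 7), sp)[[1]],
                   unname(sp$mean_shape), 1e-12)
  # full-rank round trip
  K <- ncol(sp$basis)
  rec_full <- reconstruct_shape(sp$scores, sp)
  err_full <- reconstruction_error(rec_full, gpa_frames)
  expect_lt(err_full$max, 1e-8)
  # K = 7 round-trip error equals the energy in the discarded components:
  # mean squared coordinate error = sum_{k>7} lambda_k (checked per the
  # Parseval identity, population covariance convention)
  rec7 <- reconstruct_shape(sp$scores[, 1:7], sp)
  msq <- mean(vapply(seq_along(rec7), function(i)
    sum((rec7[[i]] - gpa_frames[[i]])^2), numeric(1)))
  lam_disc <- sum(sp$eigenvalues[8:K]) * (sp$n_frames - 1) / sp$n_frames
  expect_equal(msq, lam_disc, tolerance = 1e-6)
  # error is monotonically non-increasing in K
  errs <- vapply(c(3, 5, 7, 12, K), function(k)
    reconstruction_error(reconstruct_shape(sp$scores[, 1:k, drop = FALSE],
                                           sp), gpa_frames)$mean, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  # marker-offset arithmetic
  recon <- list(rest); truth <- list(rest)
  truth[[1]]["tip", ] <- truth[[1]]["tip", ] + c(0.3, 0, 0)
  re <- reconstruction_error(recon, truth)
  expect_equal(re$mean, 0.3 / 7, tolerance = 1e-12)
})

test_that("shape scores are invariant to rigid motion of the raw frames", {
  frames <- make_shape_frames(35)
  sp1 <- shape_pca(frames)
  sp2 <- shape_pca(apply_rigid(frames, seed = 6))
  s1 <- project_scores(frames, sp1, k = 5)
  s2 <- project_scores(apply_rigid(frames, seed = 6), sp2, k = 5)
  for (k in 1:5) {
    agree <- min(max(abs(s1[, k] - s2[, k])), max(abs(s1[, k] + s2[, k])))
    expect_lt(agree, 1e-6)
  }
})

test_that("a deformation-free dataset has numerically zero shape eigenvalues", {
  cfg <- small_config(deformation_amplitudes = c(flexion = 0, roll = 0,
                                                 protrusion = 0, length = 0,
                                                 width = 0, swallow = 0),
                      n_trials = 7, seed = 3)
  sim <- simulate_kinematics(cfg)
  frames <- tonguekin:::as_frame_list(sim$markers[[1]]$positions)
  frames <- frames[seq(1, length(frames), by = 10)]
  sp <- shape_pca(frames, allow_scale = TRUE)
  # eigenvalues of unit-size aligned shapes: centroid size is 1
  expect_lt(max(sp$eigenvalues), 1e-10)
})
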