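# Standard kinematic variables: filtering, angles, distances.

make_traj <- function(frames_list, markers = tongue_markers(), fr = 200) {
  pos <- array(NA_real_, c(length(frames_list), 3, length(markers)))
  for (i in seq_along(frames_list)) pos[i, , ] <- t(frames_list[[i]])
  marker_trajectories(pos, markers, frame_rate = fr)
}

rest <- tonguekin:::rest_constellation()

test_that("zero-lag Butterworth filter has the advertised magnitude response", {
  fr <- 200
  t <- seq(0, 5, by = 1 / fr)
  # DC passthrough
  expect_equal_tol(lowpass_filter(rep(3.7, 500), 30, fr), 3.7, 1e-9)
  # 1 Hz passes with < 1% attenuation
  x1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_filter(x1, 30, fr)
  mid <- 200:800
  expect_gt(max(abs(y1[mid])) / max(abs(x1[mid])), 0.99)
  # 90 Hz attenuated > 95%
  x9 <- sin(2 * pi * 90 * t)
  y9 <- lowpass_filter(x9, 30, fr)
  expect_lt(max(abs(y9[mid])) / max(abs(x9[mid])), 0.05)
  # zero phase lag: cross-correlation of filtered 1 Hz peaks at lag 0
  cc <- stats::ccf(y1, x1, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(lowpass_filter(1:5, 30, fr), "too short")
})

test_that("jaw pitch extracts rotation about the condylar axis", {
  condyle <- rbind(c(-35, 8, -12), c(-35, 8, 12))  # axis along Z
  nf <- 5
  id <- array(rep(diag(4), nf), c(4, 4, nf))
  cran <- rigid_transforms(id, "cranium")
  # mandible == cranium motion -> pitch identically 0
  expect_equal_tol(jaw_pitch(rigid_transforms(id, "mandible"), cran, condyle),
                   0, 1e-12)
  # constructed 12 degree rotation about the condylar axis
  ang <- deg2rad_test(12)
  arr <- id
  for (i in seq_len(nf)) arr[1:3, 1:3, i] <- tonguekin:::rot_axis(c(0, 0, 1),
                                                                  ang)
  expect_equal_tol(jaw_pitch(rigid_transforms(arr, "mandible"), cran, condyle),
                   12, 1e-6)
  # rotation about an orthogonal axis projects to ~0 pitch
  arr2 <- id
  for (i in seq_len(nf)) arr2[1:3, 1:3, i] <- tonguekin:::rot_axis(c(0, 1, 0),
                                                                   ang)
  expect_equal_tol(jaw_pitch(rigid_transforms(arr2, "mandible"), cran,
                             condyle), 0, 1e-6)
  # additivity for composed rotations about the axis
  arr3 <- id
  a1 <- deg2rad_test(7); a2 <- deg2rad_test(4)
  for (i in seq_len(nf))
    arr3[1:3, 1:3, i] <- tonguekin:::rot_axis(c(0, 0, 1), a1) %*%
      tonguekin:::rot_axis(c(0, 0, 1), a2)
  expect_equal_tol(jaw_pitch(rigid_transforms(arr3, "mandible"), cran,
                             condyle), 11, 1e-6)
})

test_that("sagittal flexion matches planar-angle oracles", {
  f <- rest
  # collinear: put tip, middle midpoint and posterior_deep on one line
  f2 <- f
  mid <- colMeans(f[c("middle_superficial_R", "middle_superficial_L"), ])
  dirv <- mid - f["posterior_deep", ]
  f2["tip", ] <- mid + 2 * dirv
  expect_equal_tol(sagittal_flexion(make_traj(list(f2))), 180, 1e-6)
  # right angle construction at the vertex
  f3 <- f
  f3[c("middle_superficial_R", "middle_superficial_L"), ] <-
    rbind(c(0, 0, 1), c(0, 0, -1))
  f3["posterior_deep", ] <- c(5, 0, 0)
  f3["tip", ] <- c(0, 7, 0)
  expect_equal_tol(sagittal_flexion(make_traj(list(f3))), 90, 1e-9)
  # random triples against an independent acos oracle
  set.seed(7)
  for (i in 1:20) {
    f4 <- f
    f4["tip", ] <- stats::rnorm(3, sd = 10)
    f4["posterior_deep", ] <- stats::rnorm(3, sd = 10)
    v <- colMeans(f4[c("middle_superficial_R", "middle_superficial_L"), ])
    a <- f4["tip", ] - v; b <- f4["posterior_deep", ] - v
    oracle <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
    expect_equal_tol(sagittal_flexion(make_traj(list(f4))), oracle, 1e-9)
  }
  # coincident markers flagged as NA with a warning naming the frame
  f5 <- f
  f5["tip", ] <- colMeans(f5[c("middle_superficial_R",
                               "middle_superficial_L"), ])
  expect_warning(out <- sagittal_flexion(make_traj(list(f5, f))),
                 "frames: 1")
  expect_true(is.na(out[1]) && !is.na(out[2]))
})

test_that("protrusion is the anterior-marker mean X and is roll-invariant", {
  f <- rest
  f["tip", 1] <- 1
  f["anterior_superficial_R", 1] <- 2
  f["anterior_superficial_L", 1] <- 3
  expect_equal(protrusion(make_traj(list(f))), 2)
  # rigid +5 mm anteroposterior translation
  f2 <- sweep(rest, 2, c(5, 0, 0), "+")
  expect_equal_tol(protrusion(make_traj(list(f2))) -
                     protrusion(make_traj(list(rest))), 5, 1e-12)
  # pure roll about an anteroposterior axis leaves protrusion unchanged
  ctr <- colMeans(rest)
  R <- tonguekin:::rot_x(deg2rad_test(23))
  f3 <- sweep(sweep(rest, 2, ctr) %*% t(R), 2, ctr, "+")
  dimnames(f3) <- dimnames(rest)
  expect_equal_tol(protrusion(make_traj(list(f3))),
                   protrusion(make_traj(list(rest))), 1e-9)
})

test_that("tongue roll recovers injected rotations about the A-P axis", {
  # identity fit
  expect_equal_tol(tongue_roll(make_traj(list(rest)), rest), 0, 1e-9)
  # exact recovery across the open (-90, 90) range
  for (th in c(-89, -45, -10, 0.5, 10, 33, 89)) {
    R <- tonguekin:::rot_x(deg2rad_test(th))
    f <- rest %*% t(R)
    rownames(f) <- rownames(rest)
    expect_equal_tol(tongue_roll(make_traj(list(f)), rest), th, 1e-6)
  }
  # jittered recovery within 0.5 degrees, cross-checked against an
  # independent orthogonal-Procrustes oracle (cross-covariance SVD with
  # determinant correction)
  set.seed(13)
  anterior <- setdiff(rownames(rest), "posterior_deep")
  for (i in 1:10) {
    R <- tonguekin:::rot_x(deg2rad_test(10))
    f <- rest %*% t(R) + matrix(stats::rnorm(21, sd = 0.05), 7, 3)
    rownames(f) <- rownames(rest)
    got <- tongue_roll(make_traj(list(f)), rest)
    expect_lt(abs(got - 10), 0.5)
    A <- scale(rest[anterior, ], scale = FALSE)
    B <- scale(f[anterior, ], scale = FALSE)
    sv <- svd(crossprod(A, B))
    Ro <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    oracle <- atan2(-Ro[2, 3], Ro[3, 3]) * 180 / pi
    expect_equal_tol(got, oracle, 1e-6)
  }
  # collinear reference is rejected with the frame named
  flat <- rest; flat[, 2:3] <- 0
  expect_error(tongue_roll(make_traj(list(flat)), flat), "frame 1")
})

test_that("marker pair distances follow Euclidean geometry", {
  f <- rest
  f["middle_superficial_R", ] <- c(0, 0, 0)
  f["middle_superficial_L", ] <- c(3, 4, 0)
  d <- marker_distances(make_traj(list(f)))
  expect_equal(d$middle_width, 5)
  # isometry under a random rigid motion
  set.seed(3)
  R <- random_rotation()
  f2 <- sweep(rest %*% t(R), 2, c(4, -2, 1), "+")
  dimnames(f2) <- dimnames(rest)
  expect_equal_tol(as.matrix(marker_distances(make_traj(list(f2)))),
                   as.matrix(marker_distances(make_traj(list(rest)))), 1e-9)
  # uniform scaling about the centroid scales every distance
  ctr <- colMeans(rest)
  f3 <- sweep(sweep(rest, 2, ctr) * 1.1, 2, ctr, "+")
  dimnames(f3) <- dimnames(rest)
  expect_equal_tol(as.matrix(marker_distances(make_traj(list(f3)))),
                   1.1 * as.matrix(marker_distances(make_traj(list(rest)))),
                   1e-9)
  expect_error(marker_distances(make_traj(list(rest)),
                                pairs = list(bad = c("tip", "nope"))),
               "unknown marker")
})

test_that("standard variable set: rigid-motion invariance and variance isolation", {
  cfg <- small_config(seed = 17)
  sim <- simulate_kinematics(cfg)
  tr <- 2
  kv <- compute_standard_variables(sim$markers[[tr]], sim$mandible[[tr]],
                                   sim$cranium[[tr]],
                                   reference = sim$ground_truth$rest)
  expect_s3_class(kv, "kinematic_variables")
  expect_length(intersect(standard_variables(), names(kv)), 7)
  # apply one global proper rigid motion to all markers and the reference
  set.seed(8)
  R <- random_rotation(); tvec <- c(10, -6, 3)
  pos <- sim$markers[[tr]]$positions
  pos2 <- pos
  for (i in seq_len(dim(pos)[1]))
    pos2[i, , ] <- t(sweep(t(pos[i, , ]) %*% t(R), 2, tvec, "+"))
  mk2 <- marker_trajectories(pos2, sim$markers[[tr]]$markers, 200)
  ref2 <- sweep(sim$ground_truth$rest %*% t(R), 2, tvec, "+")
  rownames(ref2) <- rownames(sim$ground_truth$rest)
  kv2 <- compute_standard_variables(mk2, sim$mandible[[tr]],
                                    sim$cranium[[tr]], reference = ref2,
                                    axes = R)
  for (v in c("sagittal_flexion", "roll", "anterior_length", "middle_length",
              "anterior_width", "middle_width"))
    expect_equal_tol(kv2[[v]], kv[[v]], 1e-7)
})
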