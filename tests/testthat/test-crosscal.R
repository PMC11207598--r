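test_that("camera-point preprocessing applies the documented steps", {
  # offset step alone moves the origin to (0, 0, -3000)
  p <- preprocess_camera_points(matrix(0, 1, 3), mirror_fold = FALSE,
                                frame_convention = FALSE)
  expect_equal(drop(p), c(0, 0, -3000))
  # full preprocessing then its exact inverse is the identity
  set.seed(2)
  x <- matrix(rnorm(45, sd = 100), 15, 3)
  expect_equal(unpreprocess_camera_points(preprocess_camera_points(x)), x,
               tolerance = 1e-9)
})

test_that("preprocessing leaves only a small residual transform", {
  # points generated with the nominal mirror/frame/offset geometry plus a
  # small residual: after preprocessing the recovered transform is small
  phantom <- phantom_spec()
  resid_true <- pose_to_transform(pose6dof(-6, -18, -67, pitch = -5,
                                           yaw = 0.2, roll = 4.6))
  X_mri <- phantom$wells
  X_cam <- unpreprocess_camera_points(
    apply_transform(invert_transform(resid_true), X_mri))
  fit <- solve_rigid_transform(point_correspondences(
    preprocess_camera_points(X_cam), X_mri))
  pose <- transform_to_pose(fit$transform)
  expect_true(all(abs(unclass(pose)[4:6]) < 10))
  expect_true(all(abs(unclass(pose)[1:3]) < 100))
})

test_that("SVD rigid registration is exact on noiseless correspondences", {
  set.seed(1)
  for (n in c(3, 5, 15)) {
    R <- euler_to_matrix(runif(1, -60, 60), runif(1, -60, 60),
                         runif(1, -60, 60))
    t <- runif(3, -50, 50)
    src <- matrix(rnorm(3 * n, sd = 40), n, 3)
    tgt <- src %*% t(R) + matrix(t, n, 3, byrow = TRUE)
    fit <- solve_rigid_transform(list(source = src, target = tgt))
    expect_lt(max(abs(fit$transform$R - R)), 1e-9)
    expect_lt(max(abs(fit$transform$t - t)), 1e-9)
    expect_lt(fit$fre, 1e-9)
    expect_equal(det(fit$transform$R), 1, tolerance = 1e-9)
  }
})

test_that("identity correspondences give identity transform and zero FRE", {
  x <- phantom_spec()$wells
  fit <- solve_rigid_transform(list(source = x, target = x))
  expect_equal(fit$transform$R, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$fre, 0, tolerance = 1e-12)
})

test_that("degenerate and reflected configurations are handled", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(solve_rigid_transform(list(source = line, target = line)),
               "degenerate|collinear")
  # near-planar noisy sets never produce a reflection
  set.seed(9)
  for (i in 1:20) {
    src <- cbind(rnorm(4, sd = 10), rnorm(4, sd = 10), rnorm(4, sd = 1e-4))
    tgt <- src[sample(1:4), ] + rnorm(12)
    fit <- tryCatch(solve_rigid_transform(list(source = src, target = tgt)),
                    error = function(e) NULL)
    if (!is.null(fit)) expect_equal(det(fit$transform$R), 1,
                                    tolerance = 1e-9)
  }
})

test_that("registration is invariant to pair relabelling", {
  set.seed(4)
  phantom <- phantom_spec()
  src <- phantom$wells + matrix(rnorm(45, 0, 0.2), ncol = 3)
  tgt <- apply_transform(pose_to_transform(pose6dof(2, -1, 3, 1, -2, 4)),
                         phantom$wells) + matrix(rnorm(45, 0, 0.2), ncol = 3)
  f1 <- solve_rigid_transform(point_correspondences(src, tgt,
                                                    phantom$labels))
  o <- sample(1:15)
  f2 <- solve_rigid_transform(point_correspondences(src[o, ], tgt[o, ],
                                                    phantom$labels[o]))
  expect_equal(f1$transform$R, f2$transform$R, tolerance = 1e-12)
  expect_equal(f1$transform$t, f2$transform$t, tolerance = 1e-12)
})

test_that("redundant points can be dropped without changing the solution", {
  set.seed(6)
  phantom <- phantom_spec()
  tf <- pose_to_transform(pose6dof(5, -3, 7, pitch = 3, yaw = -6, roll = 9))
  src <- phantom$wells
  tgt <- apply_transform(tf, src)
  full <- solve_rigid_transform(list(source = src, target = tgt))
  keep <- c(1, 8, 13)                       # a non-collinear 3-subset
  sub <- solve_rigid_transform(list(source = src[keep, ],
                                    target = tgt[keep, ]))
  expect_lt(max(abs(full$transform$R - sub$transform$R)), 1e-9)
  expect_lt(max(abs(full$transform$t - sub$transform$t)), 1e-9)
})

test_that("FRE grows from exact to noisy and shrinks with more points", {
  set.seed(8)
  fre3 <- fre15 <- numeric(30)
  for (i in 1:30) {
    tf <- pose_to_transform(pose6dof(1, 2, -1, 2, 1, -3))
    make <- function(n) {
      src <- matrix(rnorm(3 * n, sd = 40), n, 3)
      tgt <- apply_transform(tf, src) + matrix(rnorm(3 * n, 0, 0.2), n, 3)
      solve_rigid_transform(list(source = src, target = tgt))
    }
    fre3[i] <- make(3)$fre
    fre15[i] <- make(15)$fre
  }
  expect_true(all(fre3 >= 0))
  # 3-point fits interpolate more of the noise than 15-point fits
  expect_lt(mean(fre3), mean(fre15))
  expect_gt(mean(fre15), 0.1)
})

test_that("SVD solution matches the brute-force least-squares oracle", {
  set.seed(12)
  for (i in 1:5) {
    src <- matrix(rnorm(9, sd = 30), 3, 3)
    tgt <- apply_transform(pose_to_transform(pose6dof(2, -4, 1, 3, -2, 5)),
                           src) + matrix(rnorm(9, 0, 0.2), 3, 3)
    fit <- solve_rigid_transform(list(source = src, target = tgt))
    ssd_svd <- sum((apply_transform(fit$transform, src) - tgt)^2)
    oracle <- rigid_lsq_oracle(src, tgt)
    expect_lte(ssd_svd, oracle$value + 1e-6)
  }
})

test_that("repeatability statistics summarise trial-to-trial deviations", {
  id <- rigid_transform()
  expect_error(repeatability(list(id)), "at least 2")
  r <- repeatability(list(id, id, id))
  expect_true(all(r$max_dev == 0))
  # two trials differing by 1 mm in Z only
  shifted <- rigid_transform(diag(3), c(0, 0, 1))
  r2 <- repeatability(list(id, shifted))
  expect_equal(r2["tz", "max_dev"], 0.5)
  expect_equal(sum(r2$max_dev) - r2["tz", "max_dev"], 0)
})

test_that("five noisy phantom trials stay within 1 mm and 1 degree", {
  sim <- crosscal_repeatability_sim(n_trials = 5, noise_sd = 0.3, seed = 2)
  expect_true(all(sim$repeatability$max_dev[1:3] < 1))
  expect_true(all(sim$repeatability$max_dev[4:6] < 1))
})
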