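test_that("calibration protocol enumerates the 50 placements in order", {
  p1 <- generate_calibration_protocol()
  p2 <- generate_calibration_protocol()
  expect_identical(p1, p2)                       # deterministic
  expect_equal(nrow(p1), 50)
  counts <- table(p1$grid_cell)
  expect_equal(unname(counts[["centre"]]), 10)   # 5 + 4 compound + 1 forward
  for (cell in setdiff(names(counts), "centre"))
    expect_equal(unname(counts[[cell]]), 5)
  # the compound tilts come after the nine-cell sweep, forward last
  expect_equal(p1$tilt[46:50],
               c("top-left", "top-right", "bottom-left", "bottom-right",
                 "none"))
})

test_that("intrinsics are recovered from noiseless synthetic views", {
  board <- calibration_board_spec()
  cam_true <- fix_cam()
  obs <- simulate_calibration_views(board, cam_true, noise_sd = 0)
  fit <- estimate_intrinsics(obs, board)
  expect_lt(abs(fit$intrinsics$fx - cam_true$fx) / cam_true$fx, 1e-3)
  expect_lt(abs(fit$intrinsics$fy - cam_true$fy) / cam_true$fy, 1e-3)
  expect_lt(fit$reproj_rms, 0.01)
})

test_that("reprojection error reflects the injected corner noise", {
  board <- calibration_board_spec()
  obs <- simulate_calibration_views(board, fix_cam(), noise_sd = 0.2,
                                    seed = 3)
  fit <- estimate_intrinsics(obs, board)
  expect_gt(fit$reproj_rms, 0.12)
  expect_lt(fit$reproj_rms, 0.3)
  expect_length(fit$per_view_rms, 50)
})

test_that("degenerate view sets are refused", {
  board <- calibration_board_spec()
  proto <- generate_calibration_protocol()
  proto$tilt <- "none"                           # all fronto-parallel
  obs <- simulate_calibration_views(board, fix_cam(), protocol = proto)
  expect_error(estimate_intrinsics(obs, board), "degenerate")
  expect_error(estimate_intrinsics(obs[1:5], board), "at least 10")
})

test_that("stereo extrinsics recover the generating rig", {
  board <- calibration_board_spec()
  rig <- fix_rig()
  obs <- simulate_calibration_views(board, rig, noise_sd = 0, seed = 2)
  fit <- estimate_stereo_extrinsics(obs, board, rig$left, rig$right)
  expect_equal(fit$baseline, 600, tolerance = 1)
  rot_err <- acos(pmin(1, (sum(diag(t(fit$extrinsic$R) %*%
                                      rig$extrinsic$R)) - 1) / 2)) * 180 / pi
  expect_lt(rot_err, 0.05)
  expect_lt(sqrt(sum((fit$extrinsic$t - rig$extrinsic$t)^2)), 0.5)
  # identity rig recovers an identity transform
  obs_same <- lapply(obs, function(v) list(left = v$left, right = v$left))
  fit_id <- estimate_stereo_extrinsics(obs_same, board, rig$left, rig$left)
  expect_lt(max(abs(fit_id$extrinsic$t)), 1e-6)
  expect_equal(fit_id$extrinsic$R, diag(3), tolerance = 1e-8)
})

test_that("noisy stereo calibration stays within the reprojection budget", {
  board <- calibration_board_spec()
  rig <- fix_rig()
  obs <- simulate_calibration_views(board, rig, noise_sd = 0.2, seed = 4)
  fit <- estimate_stereo_extrinsics(obs, board, rig$left, rig$right)
  expect_lt(fit$reproj_rms, 3)
  expect_equal(fit$baseline, 600, tolerance = 5)
})

test_that("unpaired stereo observations are rejected", {
  board <- calibration_board_spec()
  rig <- fix_rig()
  obs <- simulate_calibration_views(board, rig, noise_sd = 0, seed = 2)[1:5]
  obs[[3]]$right <- NULL
  expect_error(estimate_stereo_extrinsics(obs, board, rig$left, rig$right),
               "unpaired|mismatched")
})
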