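test_that("renders are deterministic and bounded", {
  spec <- fix_spec(); cam <- fix_cam()
  opts <- render_options(noise_sd = 1, seed = 99, supersample = 2)
  f1 <- render_marker_view(pose6dof(), cam, spec, opts)
  f2 <- render_marker_view(pose6dof(), cam, spec, opts)
  expect_identical(f1$pixels, f2$pixels)
  expect_gte(min(f1$pixels), 0)
  expect_lte(max(f1$pixels), 255)
  expect_equal(dim(f1$pixels), c(480, 720))
})

test_that("a marker outside the field of view is an error", {
  expect_error(render_marker_view(pose6dof(tx = 500), fix_cam(),
                                  fix_spec()),
               "field of view")
})

test_that("rendered moire beat period matches the grating difference", {
  f0 <- fix_marker_frame("identity", pose6dof())
  spec <- fix_spec()
  det <- detect_aruco(f0, spec)
  rect <- rectify_marker(f0, det, spec)
  for (g in list(spec$gratings$yaw_fine, spec$gratings$yaw_coarse)) {
    prof <- extract_moire_profile(rect, g, spec)
    # periodogram peak below the printed carrier band (the raw profile
    # still contains the carrier lines) vs f_front - f_back; the
    # attainable precision is one FFT bin
    n <- length(prof$values)
    sp <- Mod(fft(prof$values - mean(prof$values)))[2:floor(n / 2)]
    fmax <- g$f_back / 2 * prof$mm_per_px          # cycles/px cap
    keep <- seq_along(sp) / n <= fmax
    fhat <- (which.max(sp[keep])) / n / prof$mm_per_px
    bin <- 1 / n / prof$mm_per_px
    expect_lt(abs(fhat - beat_frequency(g)), 1.5 * bin)
  }
})

test_that("stereo renders respect the rig's epipolar geometry", {
  spec <- fix_spec(); rig <- fix_rig()
  # fundamental-matrix oracle from the known rig
  E <- rig$extrinsic
  Rr <- t(E$R); tr <- -drop(t(E$R) %*% E$t)     # left -> right
  Fm <- t(solve(K_mat(rig$right))) %*% moirepose:::skew(tr) %*% Rr %*%
    solve(K_mat(rig$left))
  pose <- pose6dof(yaw = 0.3)
  obj <- checkerboard_corners(spec)
  Xw <- apply_transform(pose_to_transform(pose), obj)
  pl <- project_points(Xw, rig$left, rig$mount_left)
  pr <- project_points(Xw, rig$right, rig$mount_right)
  for (i in seq_len(nrow(pl))) {
    l <- Fm %*% c(pl[i, ], 1)
    d <- abs(sum(l * c(pr[i, ], 1))) / sqrt(l[1]^2 + l[2]^2)
    expect_lt(d, 0.1)
  }
  # and the rendered images actually contain the marker in both views
  s <- render_stereo(pose, rig, spec, render_options(supersample = 2))
  expect_false(detect_aruco(s$left, spec)$occluded)
  expect_false(detect_aruco(s$right, spec)$occluded)
})

test_that("pixel noise degrades but does not bias recovered angles", {
  # mean recovered yaw over fresh noise realisations stays centred
  f0 <- fix_marker_frame("identity", pose6dof())
  f1 <- fix_marker_frame("yaw05", pose6dof(yaw = 0.5))
  spec <- fix_spec()
  gr <- moirepose:::gratings_for_axis(spec, "yaw")
  set.seed(21)
  est <- replicate(12, {
    a0 <- analyze_marker_frame(add_frame_noise(f0, 1), spec,
                               corners = FALSE, threshold = 120,
                               axes = "yaw")
    a1 <- analyze_marker_frame(add_frame_noise(f1, 1), spec,
                               corners = FALSE, threshold = 120,
                               axes = "yaw")
    as.numeric(through_plane_rotation(
      list(fine = a1$phases$yaw_fine, coarse = a1$phases$yaw_coarse),
      list(fine = a0$phases$yaw_fine, coarse = a0$phases$yaw_coarse), gr))
  })
  expect_equal(mean(est), 0.5, tolerance = 0.01)
  expect_gt(sd(est), 0)
})

test_that("occlusion and glare options alter the rendered scene", {
  spec <- fix_spec(); cam <- fix_cam()
  opts <- render_options(occlusion = list(c(60, 200, 40, 160)),
                         supersample = 2)
  f <- render_marker_view(pose6dof(), cam, spec, opts)
  det <- detect_aruco(f, spec)
  expect_true(det$occluded)                      # an anchor was painted out
  optg <- render_options(glare = list(c(360, 240, 40, 30, 120)),
                         supersample = 2)
  fg <- render_marker_view(pose6dof(), cam, spec, optg)
  f0 <- fix_marker_frame("identity", pose6dof())
  expect_gt(mean(fg$pixels[200:280, 320:400]),
            mean(f0$pixels[200:280, 320:400]))
})

test_that("a blank frame is flagged occluded", {
  blank <- new_frame(matrix(128, 480, 720))
  expect_true(detect_aruco(blank, fix_spec())$occluded)
})
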