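test_that("all four anchors are detected with sub-pixel corners", {
  spec <- fix_spec(); cam <- fix_cam(); view <- fix_view()
  f0 <- fix_marker_frame("identity", pose6dof())
  det <- detect_aruco(f0, spec)
  expect_false(det$occluded)
  expect_setequal(vapply(det$detections, `[[`, 0, "id"),
                  vapply(spec$aruco_anchors, `[[`, 0, "id"))
  ideal <- anchor_corners(spec)
  for (d in det$detections) {
    gt <- project_points(ideal[[as.character(d$id)]], cam, view)
    expect_lt(max(sqrt(rowSums((d$corners - gt)^2))), 0.5)
  }
})

test_that("masking one anchor flags the frame occluded", {
  spec <- fix_spec()
  opts <- render_options(occlusion = list(c(80, 180, 50, 140)),
                         supersample = 2)
  f <- render_marker_view(pose6dof(), fix_cam(), spec, opts)
  det <- detect_aruco(f, spec)
  expect_true(det$occluded)
  expect_lt(length(det$detections), 4)
  expect_error(rectify_marker(f, det, spec), "occluded")
})

test_that("rectification maps anchors onto their flat-marker positions", {
  spec <- fix_spec()
  for (label in c("identity", "yaw10")) {
    pose <- if (label == "identity") pose6dof() else pose6dof(yaw = 10)
    f <- fix_marker_frame(label, pose)
    det <- detect_aruco(f, spec)
    rect <- rectify_marker(f, det, spec)
    # detected anchor corners mapped through H^-1 land on the template
    ideal <- anchor_corners(spec)
    Hinv <- solve(rect$H)
    for (d in det$detections) {
      back <- moirepose:::apply_homography(Hinv, d$corners)
      gt <- ideal[[as.character(d$id)]][, 1:2]
      # 0.5 px at the rectification scale
      expect_lt(max(sqrt(rowSums((back - gt)^2))) * rect$scale, 0.5)
    }
  }
})

test_that("refined checkerboard corners match projected ground truth", {
  spec <- fix_spec(); cam <- fix_cam(); view <- fix_view()
  f0 <- fix_marker_frame("identity", pose6dof())
  det <- detect_aruco(f0, spec)
  crn <- detect_checker_corners(f0, det, spec)
  gt <- project_points(checkerboard_corners(spec), cam, view)
  expect_lt(max(sqrt(rowSums((crn - gt)^2))), 0.5)
})

test_that("profile averaging implements the line mean", {
  spec <- fix_spec()
  # hand example: two 2-sample lines averaged
  g <- moire_grating_pair(3, 1, axis = "yaw", region = c(0, 2, 0, 2))
  rect <- structure(list(pixels = rbind(c(1, 3), c(3, 5)), scale = 1,
                         origin = c(0, 2), H = diag(3)),
                    class = "rectified_marker")
  sp <- marker_spec()
  prof <- extract_moire_profile(rect, g, sp)
  expect_equal(prof$values, c(2, 4))
  expect_equal(prof$n_lines, 2)
  # constant region averages to the constant
  rectc <- structure(list(pixels = matrix(100, 10, 20), scale = 1,
                          origin = c(0, 10), H = diag(3)),
                     class = "rectified_marker")
  gc2 <- moire_grating_pair(3, 1, axis = "yaw", region = c(0, 20, 0, 10))
  profc <- extract_moire_profile(rectc, gc2, sp)
  expect_true(all(profc$values == 100))
  expect_equal(profc$n_lines, 10)
  # region outside the rectified image errors
  gout <- moire_grating_pair(3, 2.8, axis = "yaw", region = c(-50, 50, 0, 2))
  expect_error(extract_moire_profile(rectc, gout, sp), "outside")
})

test_that("sinusoid fitting recovers known parameters exactly", {
  s <- 0:99
  prof <- structure(list(values = 10 * sin(0.5 * s - 1.0) + 100,
                         positions = s, n_lines = 1, mm_per_px = NULL,
                         grating = NULL),
                    class = "moire_profile")
  fit <- fit_moire_phase(prof, omega0 = 0.5)
  expect_equal(fit$amplitude, 10, tolerance = 1e-6)
  expect_equal(fit$omega, 0.5, tolerance = 1e-6)
  expect_equal(fit$phase, 1.0, tolerance = 1e-6)
  expect_equal(fit$offset, 100, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-5)
  expect_false(fit$low_confidence)
})

test_that("phase recovery tolerates noise within 0.05 rad", {
  # profile length matches the pipeline's rectified strips; the phase
  # that matters downstream is the centre-referenced one that the
  # differencing uses
  s <- 0:319
  # for p = A sin(w s - phi), the centre-referenced phase is
  # phi - w * s_mid
  true_mid <- moirepose:::wrap_pi(1.0 - 0.5 * mean(s))
  set.seed(17)
  errs <- replicate(100, {
    v <- 10 * sin(0.5 * s - 1.0) + 100 + rnorm(length(s), 0, 2)
    prof <- structure(list(values = v, positions = s, n_lines = 1,
                           mm_per_px = NULL, grating = NULL),
                      class = "moire_profile")
    fit <- fit_moire_phase(prof, omega0 = 0.5)
    abs(moirepose:::wrap_pi(fit$phase_mid - true_mid))
  })
  expect_lt(max(errs), 0.05)
})

test_that("flat profiles are flagged low confidence", {
  s <- 0:99
  prof <- structure(list(values = rep(100, 100), positions = s,
                         n_lines = 1, mm_per_px = NULL, grating = NULL),
                    class = "moire_profile")
  fit <- fit_moire_phase(prof, omega0 = 0.5)
  expect_true(fit$low_confidence)
})

test_that("through-plane rotation recovers commanded angles", {
  spec <- fix_spec()
  a0 <- fix_analysis("identity", pose6dof())
  gr <- moirepose:::gratings_for_axis(spec, "yaw")
  # current = reference gives zero
  cur <- list(fine = a0$phases$yaw_fine, coarse = a0$phases$yaw_coarse)
  expect_equal(as.numeric(through_plane_rotation(cur, cur, gr)), 0,
               tolerance = 1e-9)
  # commanded +0.5 degree yaw
  a1 <- fix_analysis("yaw05", pose6dof(yaw = 0.5))
  th <- through_plane_rotation(
    list(fine = a1$phases$yaw_fine, coarse = a1$phases$yaw_coarse),
    list(fine = a0$phases$yaw_fine, coarse = a0$phases$yaw_coarse), gr)
  expect_equal(as.numeric(th), 0.5, tolerance = 0.05)
  # commanded 0.1 degree pitch via the pitch pair
  ap <- fix_analysis("pitch01", pose6dof(pitch = 0.1))
  grp <- moirepose:::gratings_for_axis(spec, "pitch")
  thp <- through_plane_rotation(
    list(fine = ap$phases$pitch_fine, coarse = ap$phases$pitch_coarse),
    list(fine = a0$phases$pitch_fine, coarse = a0$phases$pitch_coarse),
    grp)
  expect_equal(as.numeric(thp), 0.1, tolerance = 0.05)
})

test_that("coarse channel disambiguates beyond the fine wrap", {
  spec <- fix_spec()
  gr <- moirepose:::gratings_for_axis(spec, "yaw")
  ang <- 1.2 * phase_wrap_rotation(gr$fine)     # past one fine wrap
  a0 <- fix_analysis("identity", pose6dof())
  a1 <- fix_analysis("yaw_wrap", pose6dof(yaw = ang))
  th <- through_plane_rotation(
    list(fine = a1$phases$yaw_fine, coarse = a1$phases$yaw_coarse),
    list(fine = a0$phases$yaw_fine, coarse = a0$phases$yaw_coarse), gr)
  expect_equal(as.numeric(th), ang, tolerance = 0.05)
  expect_equal(attr(th, "wraps"), 1)
  # brute-force check: the chosen wrap minimises disagreement
  sgn <- moirepose:::moire_axis_sign("yaw")
  dphi_f <- moirepose:::wrap_pi(a1$phases$yaw_fine$phase_mid -
                                a0$phases$yaw_fine$phase_mid) * sgn
  cand <- vapply(-2:2, function(k)
    rotation_from_phase(dphi_f + 2 * pi * k, gr$fine), 0)
  expect_equal(which.min(abs(cand - attr(th, "coarse"))), 4)  # k = +1
})

test_that("inconsistent fine/coarse channels raise an error", {
  pm <- function(phi) structure(list(amplitude = 10, omega = 0.1,
                                     phase = phi, phase_mid = phi,
                                     offset = 0, residual_rms = 0.1,
                                     fitted = NULL,
                                     low_confidence = FALSE),
                                class = "phase_measurement")
  gr <- moirepose:::gratings_for_axis(fix_spec(), "yaw")
  # a coarse phase that sits maximally far from every fine candidate:
  # no joint wrap assignment brings the channels into agreement
  expect_error(through_plane_rotation(
    list(fine = pm(0), coarse = pm(1.65)),
    list(fine = pm(0), coarse = pm(0)), gr), "disagree")
})

test_that("phase differencing is reference invariant", {
  spec <- fix_spec()
  gr <- moirepose:::gratings_for_axis(spec, "yaw")
  a0 <- fix_analysis("identity", pose6dof())
  a1 <- fix_analysis("yaw05", pose6dof(yaw = 0.5))
  a2 <- fix_analysis("yaw10d", pose6dof(yaw = 1.0))
  th01 <- through_plane_rotation(
    list(fine = a1$phases$yaw_fine, coarse = a1$phases$yaw_coarse),
    list(fine = a0$phases$yaw_fine, coarse = a0$phases$yaw_coarse), gr)
  th12 <- through_plane_rotation(
    list(fine = a2$phases$yaw_fine, coarse = a2$phases$yaw_coarse),
    list(fine = a1$phases$yaw_fine, coarse = a1$phases$yaw_coarse), gr)
  expect_equal(as.numeric(th01), as.numeric(th12), tolerance = 0.02)
})

test_that("recovered angle is monotone in the commanded angle", {
  spec <- fix_spec()
  gr <- moirepose:::gratings_for_axis(spec, "yaw")
  a0 <- fix_analysis("identity", pose6dof())
  angles <- c(0.1, 0.5, 1.0)
  labels <- c("yaw01", "yaw05", "yaw10d")
  rec <- vapply(seq_along(angles), function(i) {
    ai <- fix_analysis(labels[i], pose6dof(yaw = angles[i]))
    as.numeric(through_plane_rotation(
      list(fine = ai$phases$yaw_fine, coarse = ai$phases$yaw_coarse),
      list(fine = a0$phases$yaw_fine, coarse = a0$phases$yaw_coarse), gr))
  }, 0)
  expect_true(all(diff(rec) > 0))
})
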