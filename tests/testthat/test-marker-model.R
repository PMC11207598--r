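fine <- moire_grating_pair(3, 2.8)
coarse <- moire_grating_pair(1.7, 1.6, grade = "coarse")

test_that("rotation-from-phase law matches its closed form", {
  # direct evaluation of the conversion at a full phase cycle
  expect_equal(rotation_from_phase(0, fine), 0)
  expected_fine <- 1.585 * sin(atan(2 * pi / (2 * pi * 3 * 10))) * 180 / pi
  expect_equal(rotation_from_phase(2 * pi, fine), expected_fine,
               tolerance = 1e-12)
  expect_equal(phase_wrap_rotation(fine), 3.0254, tolerance = 1e-4)
  expect_equal(phase_wrap_rotation(coarse), 5.3328, tolerance = 1e-4)
})

test_that("phase conversion is an exact inverse over the principal branch", {
  phis <- seq(-2 * pi, 2 * pi, length.out = 41)
  for (g in list(fine, coarse)) {
    ang <- rotation_from_phase(phis, g)
    expect_equal(phase_from_rotation(ang, g), phis, tolerance = 1e-10)
  }
  expect_equal(rotation_from_phase(phase_from_rotation(0.7, fine), fine),
               0.7, tolerance = 1e-10)
  expect_equal(phase_from_rotation(0, fine), 0)
  expect_equal(phase_from_rotation(rotation_from_phase(pi, coarse), coarse),
               pi, tolerance = 1e-10)
})

test_that("conversion is odd and strictly monotone in phase", {
  phis <- seq(-2 * pi, 2 * pi, length.out = 201)
  ang <- rotation_from_phase(phis, fine)
  expect_equal(ang, -rev(ang), tolerance = 1e-12)          # odd
  expect_true(all(diff(ang) > 0))                          # monotone
})

test_that("small-angle linearisation is accurate below two degrees", {
  th <- seq(-2, 2, by = 0.1)
  th <- th[th != 0]
  phi <- phase_from_rotation(th, fine)
  lin <- 1.585 * phi / (2 * pi * 3 * 10) * 180 / pi
  expect_true(all(abs(lin - th) / abs(th) < 1e-3))
})

test_that("coarse pair wraps later than fine (dynamic-range ordering)", {
  expect_gt(phase_wrap_rotation(coarse), phase_wrap_rotation(fine))
  # doubling the layer separation halves the wrap angle to first order
  fine2 <- moire_grating_pair(3, 2.8, d = 20)
  expect_equal(phase_wrap_rotation(fine2) / phase_wrap_rotation(fine), 0.5,
               tolerance = 2e-3)
})

test_that("grating pair and phase conversion reject bad input", {
  expect_error(moire_grating_pair(2.8, 3), "f_front > f_back")
  expect_error(moire_grating_pair(3, 2.8, d = 0), "thickness")
  expect_error(moire_grating_pair(3, 2.8, n_refractive = 0.5), "refractive")
  expect_error(rotation_from_phase(NaN, fine), "non-finite")
  # |theta_rad| >= n is outside the invertible domain
  expect_error(phase_from_rotation(95, fine), "domain")
})

test_that("anchor dictionary codes are rotation-unique and well separated", {
  ids <- aruco_dictionary(4)
  expect_length(unique(ids), 4)
  rots <- lapply(ids, function(id) {
    b <- moirepose:::code_to_bits(id)
    lapply(0:3, function(r) {
      for (k in seq_len(r)) b <- moirepose:::rotate_bits(b)
      b
    })
  })
  all_oriented <- unlist(rots, recursive = FALSE)
  for (i in seq_along(all_oriented))
    for (j in seq_along(all_oriented)) {
      if (i >= j) next
      expect_gte(sum(xor(all_oriented[[i]], all_oriented[[j]])), 4)
    }
})

test_that("marker specification validates geometry and round-trips YAML", {
  spec <- marker_spec()
  expect_length(spec$aruco_anchors, 4)
  expect_length(spec$gratings, 4)
  # overlap with the checkerboard is rejected
  bad <- spec$gratings
  bad$yaw_fine <- moire_grating_pair(3, 2.8, region = c(-5, 5, -5, 5))
  expect_error(marker_spec(gratings = bad), "overlaps")
  # outside the face is rejected
  bad$yaw_fine <- moire_grating_pair(3, 2.8, region = c(-40, -31, 13, 21))
  expect_error(marker_spec(gratings = bad), "outside")
  path <- tempfile(fileext = ".yaml")
  write_marker_spec(spec, path)
  spec2 <- read_marker_spec(path)
  expect_equal(spec2$face_size, spec$face_size)
  expect_equal(spec2$checkerboard, spec$checkerboard)
  expect_equal(vapply(spec2$aruco_anchors, `[[`, 0, "id"),
               vapply(spec$aruco_anchors, `[[`, 0, "id"))
  expect_equal(spec2$gratings$yaw_fine$region, spec$gratings$yaw_fine$region)
  expect_equal(spec2$gratings$pitch_coarse$f_front,
               spec$gratings$pitch_coarse$f_front)
})

test_that("checkerboard and anchor geometry are placed as designed", {
  spec <- marker_spec()
  crn <- checkerboard_corners(spec)
  expect_equal(nrow(crn), (spec$checkerboard$rows - 1) *
                 (spec$checkerboard$cols - 1))
  expect_equal(colMeans(crn), c(0, 0, 0), tolerance = 1e-12)
  ac <- anchor_corners(spec)
  expect_length(ac, 4)
  for (m in ac) expect_equal(dim(m), c(4, 3))
})
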