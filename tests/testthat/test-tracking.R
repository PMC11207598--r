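test_that("fuse_pose applies the per-DOF division of labour", {
  z <- fuse_pose(pose6dof(), 0, 0, 0)
  expect_true(z$valid)
  expect_equal(max(abs(unclass(z$pose)[1:6])), 0)
  expect_equal(unname(z$methods[c("tx", "tz", "pitch")]),
               c("pnp", "dlt", "moire"))
  # occluded moire leaves a tagged partial record
  part <- fuse_pose(pose6dof(0.2, 0.1, roll = 0.3), 0.05, NA, NA)
  expect_false(part$valid)
  expect_equal(part$pose[["tx"]], 0.2)
  expect_true(all(part$methods[c("pitch", "yaw")] == "missing"))
  # a full measurement set maps onto the right slots
  f <- fuse_pose(pose6dof(0.3, -0.2, 99, pitch = 9, yaw = 9, roll = 1),
                 0.5, 0.4, -0.6)
  expect_equal(unclass(f$pose)[1:6],
               c(tx = 0.3, ty = -0.2, tz = 0.5, pitch = 0.4, yaw = -0.6,
                 roll = 1))
})

test_that("a short static stereo sequence tracks near zero", {
  spec <- fix_spec(); rig <- fix_rig()
  opts <- render_options(supersample = 2)
  s <- render_stereo(pose6dof(), rig, spec, opts)
  set.seed(31)
  fl <- lapply(0:2, function(i) {
    f <- add_frame_noise(s$left, 1); f$timestamp <- i / 30; f
  })
  fr <- lapply(0:2, function(i) {
    f <- add_frame_noise(s$right, 1); f$timestamp <- i / 30; f
  })
  tr <- track_sequence(fl, fr, spec, rig)
  expect_s3_class(tr, "pose_trace")
  expect_true(all(tr$valid))
  expect_lt(max(abs(tr$tx), abs(tr$ty), abs(tr$tz)), 0.05)
  expect_lt(max(abs(tr$pitch), abs(tr$yaw), abs(tr$roll)), 0.05)
})

test_that("a commanded yaw oscillation is recovered in the trace", {
  spec <- fix_spec(); rig <- fix_rig()
  opts <- render_options(supersample = 2)
  n <- 12
  tt <- (0:(n - 1)) / n                 # one full period
  yaw <- 1.0 * sin(2 * pi * tt)
  fl <- list(); fr <- list()
  for (i in seq_len(n)) {
    s <- render_stereo(pose6dof(yaw = yaw[i]), rig, spec, opts,
                       timestamp = tt[i])
    fl[[i]] <- s$left; fr[[i]] <- s$right
  }
  tr <- track_sequence(fl, fr, spec, rig)
  expect_true(all(tr$valid))
  # first-bin Fourier amplitude of the recovered yaw
  amp <- 2 * Mod(fft(tr$yaw - mean(tr$yaw)))[2] / n
  expect_equal(amp, 1.0, tolerance = 0.05)
  expect_equal(which.max(Mod(fft(tr$yaw - mean(tr$yaw)))[2:6]), 1)
})

test_that("the frequency-domain low-pass attenuates above the cutoff", {
  set.seed(5)
  n <- 512; fs <- 30
  noise <- matrix(rnorm(n * 6), n, 6)
  tr <- pose_trace(time = (0:(n - 1)) / fs, poses = noise)
  fl <- lowpass_trace(tr, cutoff_hz = 5, fs = fs)
  spec_before <- Mod(fft(tr$tx))^2
  spec_after <- Mod(fft(fl$tx))^2
  freqs <- (0:(n - 1)) * fs / n
  hi <- freqs > 5.5 & freqs < fs - 5.5
  lo <- freqs > 0 & freqs < 4.5
  expect_lt(sum(spec_after[hi]), sum(spec_before[hi]) * 0.01)   # > 20 dB
  expect_equal(sum(spec_after[lo]), sum(spec_before[lo]), tolerance = 1e-6)
  # traces with invalid frames are refused, not interpolated
  tr$valid[3] <- FALSE
  expect_error(lowpass_trace(tr, 5, fs), "invalid")
})

test_that("an occluded reference frame is an error", {
  spec <- fix_spec(); rig <- fix_rig()
  opts <- render_options(occlusion = list(c(80, 180, 50, 140)),
                         supersample = 2)
  s_occ <- render_stereo(pose6dof(), rig, spec, opts)
  expect_error(track_sequence(list(s_occ$left), list(s_occ$right), spec,
                              rig),
               "occluded")
})
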