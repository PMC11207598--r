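test_that("trajectory has the protocol sample count and amplitude", {
  cfg <- trajectory_config(seed = 3)
  tr <- generate_trajectory(cfg)
  expect_equal(nrow(tr), 2000)
  # noiseless trajectories reach but never exceed the 1.5 amplitude
  cfg0 <- trajectory_config(noise_sd = 0, seed = 4)
  tr0 <- generate_trajectory(cfg0)
  for (dof in c("tx", "ty", "tz", "pitch", "yaw", "roll")) {
    expect_lte(max(abs(tr0[[dof]])), 1.5 + 1e-12)
    expect_gte(max(abs(tr0[[dof]])), 1.5 * 0.995)   # discretisation only
  }
})

test_that("per-DOF dominant frequencies lie in the sampled band", {
  for (seed in 1:10) {
    tr <- generate_trajectory(trajectory_config(noise_sd = 0, seed = seed))
    for (dof in c("tx", "ty", "tz", "pitch", "yaw", "roll")) {
      f <- dominant_freq(tr[[dof]]) * 30       # Hz at the 30 Hz rate
      expect_gte(f, 1.7 - 30 / 2000)           # one FFT bin of slack
      expect_lte(f, 2.3 + 30 / 2000)
    }
  }
})

test_that("trajectories are deterministic and DOF are independent", {
  t1 <- generate_trajectory(trajectory_config(seed = 7))
  t2 <- generate_trajectory(trajectory_config(seed = 7))
  expect_identical(t1, t2)
  t3 <- generate_trajectory(trajectory_config(seed = 8))
  expect_false(identical(t1$tx, t3$tx))
  # noiseless sinusoids at mismatched frequencies decorrelate; pairs
  # that happened to draw near-identical frequencies (within two FFT
  # bins) are excluded, since equal-frequency sinusoids correlate by
  # construction
  tr <- generate_trajectory(trajectory_config(noise_sd = 0, seed = 9))
  dofs <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  fd <- vapply(dofs, function(d) dominant_freq(tr[[d]]), 0)
  for (i in 1:5) for (j in (i + 1):6) {
    if (abs(fd[i] - fd[j]) <= 2 / 2000) next
    expect_lt(abs(cor(tr[[dofs[i]]], tr[[dofs[j]]])), 0.2)
  }
})

test_that("pose pairs difference and reconstruct the trace", {
  tr <- generate_trajectory(trajectory_config(n_samples = 50, seed = 5))
  pp <- make_pose_pairs(tr)
  expect_equal(nrow(pp), 49)
  expect_equal(cumsum(pp$d_tx) + tr$tx[1], tr$tx[-1], tolerance = 1e-12)
  # hand example: positions 0, 1, 3 give deltas 1, 2
  small <- pose_trace(time = 0:2 / 30,
                      poses = cbind(c(0, 1, 3), 0, 0, 0, 0, 0))
  ps <- make_pose_pairs(small)
  expect_equal(ps$d_tx, c(1, 2))
  # constant trace gives zero deltas
  const <- pose_trace(time = 0:4 / 30, poses = matrix(2, 5, 6))
  expect_true(all(as.matrix(make_pose_pairs(const)[, 15:20]) == 0))
  expect_error(make_pose_pairs(const[1, ]), "at least 2")
})

test_that("per-step deltas obey the analytic rate bound", {
  cfg <- trajectory_config(seed = 11)
  tr <- generate_trajectory(cfg)
  pp <- make_pose_pairs(tr)
  bound <- 1.5 * 2 * pi * 2.3 / 30 + 8 * 0.05 * 1.5   # rate + noise term
  for (d in c("d_tx", "d_ty", "d_tz", "d_pitch", "d_yaw", "d_roll"))
    expect_lt(max(abs(pp[[d]])), bound)
})

test_that("invalid configurations are rejected", {
  expect_error(trajectory_config(n_samples = 1))
  expect_error(trajectory_config(freq_range = c(2.3, 1.7)))
  expect_error(generate_trajectory(list()), "trajectory_config")
})
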