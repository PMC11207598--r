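# Physiological head-motion simulation: noisy sinusoids per DOF.

#' Motion trajectory configuration
#'
#' Parameters of the simulated head motion: each of the 6 DOF follows an
#' independent sinusoid with amplitude 1.5 (mm or degrees), a frequency
#' drawn uniformly from \[1.7, 2.3\] Hz and a uniform random starting
#' phase, sampled at the 30 Hz camera frame rate, plus additive white
#' Gaussian noise. The upper frequency bound deliberately exceeds
#' ordinary in-scanner head motion so the generated poses cover a wider
#' range of states. The noise model (white Gaussian, default sigma = 5%
#' of the amplitude) is a configurable choice.
#'
#' @param amplitude per-DOF amplitude (single value or length 6; mm for
#'   translations, degrees for rotations).
#' @param freq_range frequency interval (Hz).
#' @param sample_rate sampling rate (Hz).
#' @param n_samples number of samples per DOF.
#' @param noise_sd noise standard deviation as a fraction of amplitude.
#' @param seed RNG seed (determinism contract).
#' @return object of class \code{trajectory_config}.
#' @export
trajectory_config <- function(amplitude = 1.5, freq_range = c(1.7, 2.3),
                              sample_rate = 30, n_samples = 2000,
                              noise_sd = 0.05, seed = 1) {
  if (length(amplitude) == 1) amplitude <- rep(amplitude, 6)
  stopifnot(length(amplitude) == 6, all(amplitude >= 0),
            length(freq_range) == 2, freq_range[1] > 0,
            freq_range[1] <= freq_range[2],
            n_samples >= 2, sample_rate > 0, noise_sd >= 0)
  structure(list(amplitude = amplitude, freq_range = freq_range,
                 sample_rate = sample_rate, n_samples = n_samples,
                 noise_sd = noise_sd, seed = seed),
            class = "trajectory_config")
}

#' Generate a 6-DOF motion trajectory
#'
#' Draws one noisy sinusoid per DOF (independent frequency and phase;
#' all six DOF vary simultaneously) and returns them as a pose trace.
#' Deterministic for a given config seed.
#'
#' @param config a [trajectory_config()].
#' @return a [pose_trace()] with \code{n_samples} rows.
#' @export
generate_trajectory <- function(config) {
  if (!inherits(config, "trajectory_config"))
    stop("generate_trajectory: config must be a trajectory_config")
  set.seed(config$seed)
  n <- config$n_samples
  t <- (seq_len(n) - 1) / config$sample_rate
  dof <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  vals <- sapply(seq_along(dof), function(k) {
    f <- runif(1, config$freq_range[1], config$freq_range[2])
    phi <- runif(1, 0, 2 * pi)
    a <- config$amplitude[k]
    a * sin(2 * pi * f * t + phi) + rnorm(n, 0, config$noise_sd * a)
  })
  colnames(vals) <- dof
  pose_trace(time = t, poses = vals)
}

#' Consecutive pose pairs with delta labels
#'
#' Converts a pose trace into the (pose_t, pose_t+1, delta) triples used
#' as training items for the pose-delta regressor. Deltas are
#' componentwise differences (valid in the small-angle regime of the
#' simulated amplitudes); the cumulative sum of deltas reconstructs the
#' trace exactly.
#'
#' @param trace a [pose_trace()].
#' @return data.frame with n-1 rows: columns \code{t0}, \code{t1}
#'   (indices), the pose at t0 (\code{*_0}), at t1 (\code{*_1}) and the
#'   deltas (\code{d_*}).
#' @export
make_pose_pairs <- function(trace) {
  n <- nrow(trace)
  if (n < 2) stop("make_pose_pairs: trace must have at least 2 samples")
  dof <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  P <- as.matrix(trace[, dof])
  d <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
  out <- data.frame(t0 = seq_len(n - 1), t1 = 2:n)
  for (k in seq_along(dof)) out[[paste0(dof[k], "_0")]] <- P[-n, k]
  for (k in seq_along(dof)) out[[paste0(dof[k], "_1")]] <- P[-1, k]
  for (k in seq_along(dof)) out[[paste0("d_", dof[k])]] <- d[, k]
  out
}
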