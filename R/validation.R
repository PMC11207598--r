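# Benchtop-style validation experiments on synthetic renders: the
# desk-scale analogues of moving the marker on micrometer stages and
# recording 150-frame videos at each increment.

#' Benchtop increment experiment on synthetic renders
#'
#' Renders the marker at a reference pose and at a commanded single-DOF
#' increment, then recovers the increment frame by frame under fresh
#' pixel-noise realisations of both scenes, mimicking the 150-frame
#' averaging of the physical benchtop protocol. The estimator follows
#' the division of labour of the platform: pitch/yaw via the moire
#' pipeline (with monocular PnP angles optionally recorded alongside,
#' for the instability comparison), tx/ty/roll via monocular planar PnP,
#' and tz via stereo DLT triangulation of the checkerboard corners with
#' corner-level noise.
#'
#' @param dof one of "tx", "ty", "tz", "pitch", "yaw", "roll".
#' @param delta commanded increment (mm or degrees).
#' @param n_frames frames per position.
#' @param noise_sd pixel noise (grey levels) -- or corner noise in px
#'   for the DLT depth experiment.
#' @param seed RNG seed.
#' @param spec a [marker_spec()].
#' @param rig a [stereo_rig_preset()]-style rig with mounts.
#' @param with_pnp_angles for moire DOFs, also record the per-frame
#'   monocular PnP pitch/yaw estimates on the same noisy renders.
#' @return list: \code{samples} (per-frame recovered increments),
#'   \code{mean}, \code{sd}, and for moire DOFs with
#'   \code{with_pnp_angles} also \code{pnp_samples} (n x 2, pitch/yaw).
#' @export
benchtop_increment_experiment <- function(dof, delta, n_frames = 150,
                                          noise_sd = 1, seed = 1,
                                          spec = marker_spec(),
                                          rig = stereo_rig_preset(),
                                          with_pnp_angles = FALSE) {
  set.seed(seed)
  pose0 <- pose6dof()
  args <- list(tx = 0, ty = 0, tz = 0, pitch = 0, yaw = 0, roll = 0)
  args[[dof]] <- delta
  pose1 <- do.call(pose6dof, args)
  opts0 <- render_options(noise_sd = 0)
  obj <- checkerboard_corners(spec)
  thr <- 120

  if (dof %in% c("pitch", "yaw")) {
    f0 <- render_marker_view(pose0, rig$left, spec, opts0,
                             viewing = rig$mount_left)
    f1 <- render_marker_view(pose1, rig$left, spec, opts0,
                             viewing = rig$mount_left)
    gr <- gratings_for_axis(spec, dof)
    samples <- numeric(n_frames)
    pnp_samples <- if (with_pnp_angles) matrix(0, n_frames, 2) else NULL
    for (i in seq_len(n_frames)) {
      n0 <- add_frame_noise(f0, noise_sd)
      n1 <- add_frame_noise(f1, noise_sd)
      a0 <- analyze_marker_frame(n0, spec, corners = with_pnp_angles,
                                 threshold = thr, axes = dof,
                                 min_area = 2500)
      a1 <- analyze_marker_frame(n1, spec, corners = with_pnp_angles,
                                 threshold = thr, axes = dof,
                                 min_area = 2500)
      if (a0$occluded || a1$occluded) { samples[i] <- NA; next }
      cur <- list(fine = a1$phases[[paste0(dof, "_fine")]],
                  coarse = a1$phases[[paste0(dof, "_coarse")]])
      ref <- list(fine = a0$phases[[paste0(dof, "_fine")]],
                  coarse = a0$phases[[paste0(dof, "_coarse")]])
      samples[i] <- as.numeric(through_plane_rotation(cur, ref, gr))
      if (with_pnp_angles) {
        p0 <- solve_planar_pnp(a0$corners, obj, rig$left)
        p1 <- solve_planar_pnp(a1$corners, obj, rig$left)
        rel <- relative_marker_pose(p0$transform, p1$transform)
        pnp_samples[i, ] <- unclass(rel)[c("pitch", "yaw")]
      }
    }
    out <- list(dof = dof, delta = delta, samples = samples,
                mean = mean(samples, na.rm = TRUE),
                sd = sd(samples, na.rm = TRUE))
    if (with_pnp_angles) out$pnp_samples <- pnp_samples
    return(out)
  }

  if (dof == "tz") {
    s0 <- render_stereo(pose0, rig, spec, opts0)
    s1 <- render_stereo(pose1, rig, spec, opts0)
    crn <- lapply(list(s0$left, s0$right, s1$left, s1$right), function(f) {
      det <- detect_aruco(f, spec, threshold = thr, min_area = 2500)
      detect_checker_corners(f, det, spec)
    })
    samples <- numeric(n_frames)
    for (i in seq_len(n_frames)) {
      jit <- lapply(crn, function(p)
        p + matrix(rnorm(length(p), 0, noise_sd), ncol = 2))
      X0 <- triangulate_points(jit[[1]], jit[[2]], rig)
      X1 <- triangulate_points(jit[[3]], jit[[4]], rig)
      samples[i] <- -(colMeans(X1)[3] - colMeans(X0)[3])
    }
    return(list(dof = dof, delta = delta, samples = samples,
                mean = mean(samples), sd = sd(samples)))
  }

  # in-plane DOF via monocular PnP
  f0 <- render_marker_view(pose0, rig$left, spec, opts0,
                           viewing = rig$mount_left)
  f1 <- render_marker_view(pose1, rig$left, spec, opts0,
                           viewing = rig$mount_left)
  samples <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    n0 <- add_frame_noise(f0, noise_sd)
    n1 <- add_frame_noise(f1, noise_sd)
    d0 <- detect_aruco(n0, spec, threshold = thr, min_area = 2500)
    d1 <- detect_aruco(n1, spec, threshold = thr, min_area = 2500)
    if (d0$occluded || d1$occluded) { samples[i] <- NA; next }
    c0 <- detect_checker_corners(n0, d0, spec)
    c1 <- detect_checker_corners(n1, d1, spec)
    p0 <- solve_planar_pnp(c0, obj, rig$left)
    p1 <- solve_planar_pnp(c1, obj, rig$left)
    rel <- relative_marker_pose(p0$transform, p1$transform)
    samples[i] <- unclass(rel)[[dof]]
  }
  list(dof = dof, delta = delta, samples = samples,
       mean = mean(samples, na.rm = TRUE), sd = sd(samples, na.rm = TRUE))
}

#' Simulated cross-calibration repeatability trials
#'
#' Simulates the five-trial cross-calibration protocol: a fixed true
#' residual camera-to-scanner transform (of the magnitude left after the
#' documented preprocessing), a 15-well phantom moved to a different
#' random pose within the field of view for each trial, matched point
#' sets generated on both sides with isotropic Gaussian noise, the
#' documented preprocessing applied, and the rigid transform solved per
#' trial by SVD.
#'
#' @param n_trials number of trials.
#' @param noise_sd per-point isotropic noise (mm).
#' @param seed RNG seed.
#' @param phantom a [phantom_spec()].
#' @return list: \code{trials} (transforms), \code{repeatability}
#'   (per-DOF data.frame from [repeatability()]), \code{max_dev}
#'   (largest per-DOF deviation overall), \code{true} (the generating
#'   transform).
#' @export
crosscal_repeatability_sim <- function(n_trials = 5, noise_sd = 0.3,
                                       seed = 1, phantom = phantom_spec()) {
  set.seed(seed)
  true_tf <- pose_to_transform(pose6dof(-6.31, -18.56, -67.52,
                                        pitch = -5.25, yaw = 0.18,
                                        roll = 4.62))
  inv_true <- invert_transform(true_tf)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    placement <- pose_to_transform(pose6dof(
      runif(1, -25, 25), runif(1, -25, 25), runif(1, -15, 15),
      pitch = runif(1, -8, 8), yaw = runif(1, -8, 8), roll = runif(1, -8, 8)))
    X_mri <- apply_transform(placement, phantom$wells)
    X_cam_raw <- unpreprocess_camera_points(apply_transform(inv_true, X_mri))
    src <- X_cam_raw + matrix(rnorm(length(X_mri), 0, noise_sd), ncol = 3)
    tgt <- X_mri + matrix(rnorm(length(X_mri), 0, noise_sd), ncol = 3)
    corr <- point_correspondences(preprocess_camera_points(src), tgt,
                                  labels = phantom$labels)
    trials[[k]] <- solve_rigid_transform(corr)$transform
  }
  rep <- repeatability(trials)
  list(trials = trials, repeatability = rep, max_dev = max(rep$max_dev),
       true = true_tf)
}

# ---------------------------------------------------------------------------
# markerless proof-of-concept experiment

#' Build a head-proxy training dataset
#'
#' Renders two in-bore camera views of the procedural head at every
#' trajectory sample and assembles consecutive timepoints into
#' 4-channel 180 x 120 input stacks labelled with the inter-frame pose
#' deltas.
#'
#' @param trace a [pose_trace()] (the simulated head trajectory).
#' @param params a [head_proxy_params()].
#' @param cams a [head_camera_rig()].
#' @param render_wh intermediate render size (downsampled from the
#'   in-bore camera geometry; the stack is resized to 180 x 120 either
#'   way).
#' @return object of class \code{hp_dataset}: a single-precision sample
#'   store (kept outside R's memory; see [hpnet_train()]), \code{n}
#'   samples and the \code{labels} ((n-1) x 6 delta matrix).
#' @export
build_hp_dataset <- function(trace, params, cams = head_camera_rig(),
                             render_wh = c(180, 120)) {
  n <- nrow(trace)
  dof <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  opts <- render_options(noise_sd = 0, blur_sd = 0)
  ss <- if (all(render_wh == c(180, 120))) 2L else 1L
  render_tp <- function(i) {
    pose <- do.call(pose6dof, as.list(unlist(trace[i, dof])))
    fr <- array(0, c(120, 180, 2))
    for (c in 1:2) {
      f <- render_head_proxy(pose, cams$intrinsics, params, opts,
                             viewing = cams[[paste0("cam", c)]],
                             width = render_wh[1], height = render_wh[2],
                             supersample = ss)
      fr[, , c] <- if (all(dim(f$pixels) == c(120, 180))) f$pixels / 255
                   else resize_bilinear(f$pixels / 255, 180, 120)
    }
    fr
  }
  store <- .hp_store_create(n - 1L)
  prev <- render_tp(1)
  stack <- array(0, c(120, 180, 4))
  for (i in 2:n) {
    cur <- render_tp(i)
    stack[, , 1:2] <- prev
    stack[, , 3:4] <- cur
    .hp_store_set(store, i - 1L, stack)
    prev <- cur
  }
  P <- as.matrix(trace[, dof])
  labels <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
  colnames(labels) <- dof
  structure(list(store = store, n = n - 1L, labels = labels),
            class = "hp_dataset")
}

#' Markerless proof-of-concept experiment
#'
#' The end-to-end scaled-down experiment: simulate a noisy-sinusoid head
#' trajectory (2001 samples giving 2000 consecutive pose pairs), render
#' the procedural head through the two in-bore cameras, split
#' 1400/400/200 in trajectory order (test unshuffled), min-max scale the
#' labels on train+validation only, train the convolutional regressor,
#' and evaluate per-DOF RMSE on the held-out test pairs and on 200 fresh
#' pairs of a different head proxy never seen in training.
#'
#' @param seed master seed; trajectory, head shapes and training derive
#'   their seeds from it.
#' @param epochs training epochs (the full protocol uses 100; reduced
#'   budgets should stay at 30 or more).
#' @param n_samples trajectory samples (n_samples - 1 pose pairs).
#' @param skip_unseen skip the unseen-head evaluation.
#' @return list: \code{model}, \code{seen} and \code{unseen} evaluation
#'   lists (per-DOF RMSE + average), \code{split_diag}.
#' @export
hp_proof_of_concept <- function(seed = 1, epochs = 30, n_samples = 2001,
                                skip_unseen = FALSE) {
  cfg <- trajectory_config(n_samples = n_samples, seed = seed)
  trace <- generate_trajectory(cfg)
  head_seen <- head_proxy_params(seed = seed + 11)
  cams <- head_camera_rig()
  ds <- build_hp_dataset(trace, head_seen, cams)
  split <- hpnet_train_config()$split
  if (sum(split) != ds$n)
    stop("hp_proof_of_concept: split does not match the dataset size")
  idx_train <- seq_len(split[1])
  idx_val <- split[1] + seq_len(split[2])
  idx_test <- split[1] + split[2] + seq_len(split[3])
  tc <- hpnet_train_config(epochs = epochs, seed = seed)
  model <- hpnet_train(ds, ds$labels, idx_train, idx_val, train = tc)
  seen <- evaluate_hpnet(model, ds, ds$labels[idx_test, , drop = FALSE],
                         idx = idx_test)
  diag <- split_summary(ds$labels, list(train = idx_train, val = idx_val,
                                        test = idx_test))
  out <- list(model = model, seen = seen, split_diag = diag)
  if (!skip_unseen) {
    cfg2 <- trajectory_config(n_samples = 201, seed = seed + 31)
    trace2 <- generate_trajectory(cfg2)
    head_unseen <- head_proxy_params(seed = seed + 104729)
    ds2 <- build_hp_dataset(trace2, head_unseen, cams)
    out$unseen <- evaluate_hpnet(model, ds2, ds2$labels)
  }
  out
}
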