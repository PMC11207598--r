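# 6-DOF pose assembly and sequence tracking: PnP for the in-plane DOF,
# stereo DLT for depth, moire phases for through-plane rotations.

#' Fuse per-method measurements into one 6-DOF pose
#'
#' Division of labour across methods: tx, ty and roll from the planar
#' PnP solution (the in-plane DOF it measures reliably), tz from stereo
#' DLT triangulation, pitch and yaw from the moire phase analysis. Any
#' missing component leaves the frame invalid; available components are
#' retained with their method tags so partial records (e.g. PnP-only
#' under moire occlusion) stay inspectable.
#'
#' @param pnp a [pose6dof()] relative pose from PnP (or NULL).
#' @param z_dlt depth increment from triangulation (mm, or NA).
#' @param pitch_moire,yaw_moire moire angles (deg, or NA).
#' @return list: \code{pose} ([pose6dof()], NA components where
#'   missing), \code{valid}, \code{methods} (per-DOF tags).
#' @export
fuse_pose <- function(pnp, z_dlt, pitch_moire, yaw_moire) {
  get <- function(x, f) if (is.null(x)) NA_real_ else unclass(x)[[f]]
  comp <- c(tx = get(pnp, "tx"), ty = get(pnp, "ty"),
            tz = if (is.null(z_dlt)) NA_real_ else as.numeric(z_dlt),
            pitch = if (is.null(pitch_moire)) NA_real_ else as.numeric(pitch_moire),
            yaw = if (is.null(yaw_moire)) NA_real_ else as.numeric(yaw_moire),
            roll = get(pnp, "roll"))
  methods <- c(tx = "pnp", ty = "pnp", tz = "dlt",
               pitch = "moire", yaw = "moire", roll = "pnp")
  methods[is.na(comp)] <- "missing"
  valid <- all(is.finite(comp))
  pose <- structure(comp, frame_id = "marker-ref", class = "pose6dof")
  list(pose = pose, valid = valid, methods = methods)
}

# analyse the reference frame of a session
track_reference <- function(frame_l, frame_r, spec, rig) {
  al <- analyze_marker_frame(frame_l, spec)
  if (al$occluded) stop("track_sequence: reference frame is occluded")
  ar <- analyze_marker_frame(frame_r, spec, corners = TRUE)
  if (ar$occluded) stop("track_sequence: reference frame occluded in right camera")
  obj <- checkerboard_corners(spec)
  pnp <- solve_planar_pnp(al$corners, obj, rig$left)
  X <- triangulate_points(al$corners, ar$corners, rig)
  list(analysis = al, pnp = pnp$transform, centroid = colMeans(X))
}

#' Track a stereo frame sequence
#'
#' Runs the full pipeline over paired stereo streams and returns the
#' pose trace relative to a reference frame: per frame, anchors are
#' detected, the marker rectified, moire phases fitted against the
#' reference frame's phases, planar PnP solved in the left camera, the
#' checkerboard centroid triangulated, and the components fused. Frames
#' are paired across cameras by nearest timestamp within half a frame
#' interval; unmatched or occluded frames are flagged invalid, never
#' interpolated. An optional zero-phase frequency-domain low-pass
#' (default off; 5 Hz is the platform's choice, above the simulated
#' physiological band) smooths each DOF.
#'
#' @param frames_left,frames_right lists of [new_frame()]s.
#' @param spec a [marker_spec()].
#' @param rig a calibrated [stereo_rig()].
#' @param reference_frame index of the reference (must be unoccluded).
#' @param lowpass_hz optional cutoff (Hz); NULL disables.
#' @param pair_tol pairing tolerance (s).
#' @return a [pose_trace()].
#' @export
track_sequence <- function(frames_left, frames_right, spec, rig,
                           reference_frame = 1, lowpass_hz = NULL,
                           pair_tol = 1 / 60) {
  tl <- vapply(frames_left, `[[`, 0, "timestamp")
  tr <- vapply(frames_right, `[[`, 0, "timestamp")
  match_r <- vapply(tl, function(t) {
    j <- which.min(abs(tr - t))
    if (abs(tr[j] - t) <= pair_tol) j else NA_integer_
  }, 0L)
  ref <- track_reference(frames_left[[reference_frame]],
                         frames_right[[match_r[reference_frame]]],
                         spec, rig)
  obj <- checkerboard_corners(spec)
  n <- length(frames_left)
  poses <- matrix(NA_real_, n, 6)
  valid <- logical(n)
  methods <- character(n)
  for (i in seq_len(n)) {
    if (is.na(match_r[i])) { methods[i] <- "unpaired"; next }
    al <- analyze_marker_frame(frames_left[[i]], spec)
    if (al$occluded) { methods[i] <- "occluded"; next }
    pnp <- solve_planar_pnp(al$corners, obj, rig$left)
    rel <- relative_marker_pose(ref$pnp, pnp$transform)
    ar <- analyze_marker_frame(frames_right[[match_r[i]]], spec)
    z <- NULL
    if (!ar$occluded) {
      X <- triangulate_points(al$corners, ar$corners, rig)
      z <- -(colMeans(X)[3] - ref$centroid[3])
    }
    pit <- tryCatch(through_plane_rotation(
      list(fine = al$phases$pitch_fine, coarse = al$phases$pitch_coarse),
      list(fine = ref$analysis$phases$pitch_fine,
           coarse = ref$analysis$phases$pitch_coarse),
      gratings_for_axis(spec, "pitch")), error = function(e) NULL)
    yaw <- tryCatch(through_plane_rotation(
      list(fine = al$phases$yaw_fine, coarse = al$phases$yaw_coarse),
      list(fine = ref$analysis$phases$yaw_fine,
           coarse = ref$analysis$phases$yaw_coarse),
      gratings_for_axis(spec, "yaw")), error = function(e) NULL)
    fz <- fuse_pose(rel, z, pit, yaw)
    poses[i, ] <- unclass(fz$pose)[1:6]
    valid[i] <- fz$valid
    methods[i] <- paste(fz$methods, collapse = "|")
  }
  trace <- pose_trace(tl, poses, valid = valid, methods = methods)
  if (!is.null(lowpass_hz)) {
    fs <- 1 / median(diff(tl))
    trace <- lowpass_trace(trace, lowpass_hz, fs)
  }
  trace
}

#' Zero-phase frequency-domain low-pass filter for pose traces
#'
#' Masks all Fourier components above the cutoff and inverse-transforms
#' -- zero phase delay, applied per DOF. Requires a fully valid,
#' uniformly sampled trace (invalid frames are never interpolated; the
#' filter refuses rather than fabricate samples).
#'
#' @param trace a [pose_trace()].
#' @param cutoff_hz cutoff frequency (Hz).
#' @param fs sampling rate (Hz).
#' @return the filtered \code{pose_trace}.
#' @export
lowpass_trace <- function(trace, cutoff_hz, fs) {
  if (!all(trace$valid))
    stop("lowpass_trace: trace contains invalid frames; filter only valid, gap-free traces")
  n <- nrow(trace)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)       # two-sided
  mask <- freqs <= cutoff_hz
  for (dof in c("tx", "ty", "tz", "pitch", "yaw", "roll")) {
    X <- stats::fft(trace[[dof]])
    trace[[dof]] <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  }
  trace
}
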