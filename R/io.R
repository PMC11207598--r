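# Shared containers and file I/O: frames, pose traces, calibration files.

#' Video frame
#'
#' A single grayscale frame: a height x width matrix of grey levels in
#' \[0, 255\].
#'
#' @param pixels numeric matrix (rows = image lines).
#' @param timestamp acquisition time (s).
#' @param camera_id camera label.
#' @return object of class \code{frame}.
#' @export
new_frame <- function(pixels, timestamp = 0, camera_id = "cam") {
  pixels <- as.matrix(pixels)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("new_frame: pixel values must be within [0, 255]")
  structure(list(pixels = pixels, width = ncol(pixels),
                 height = nrow(pixels), timestamp = timestamp,
                 camera_id = camera_id),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("frame: %dx%d px, t=%.3fs, camera '%s'\n",
              x$width, x$height, x$timestamp, x$camera_id))
  invisible(x)
}

#' Pose trace
#'
#' A time-stamped sequence of 6-DOF poses with validity flags and
#' per-DOF method tags.
#'
#' @param time strictly increasing timestamps (s).
#' @param poses n x 6 matrix (columns tx, ty, tz, pitch, yaw, roll).
#' @param valid logical validity flags (invalid frames carry NA poses).
#' @param methods optional character tags (e.g. "pnp+dlt+moire").
#' @return data.frame of class \code{pose_trace}.
#' @export
pose_trace <- function(time, poses, valid = NULL, methods = NULL) {
  poses <- as.matrix(poses)
  stopifnot(ncol(poses) == 6, nrow(poses) == length(time))
  if (any(diff(time) <= 0))
    stop("pose_trace: timestamps must be strictly increasing")
  if (is.null(valid)) valid <- rep(TRUE, length(time))
  if (is.null(methods)) methods <- rep("", length(time))
  if (any(!valid & !apply(poses, 1, function(r) all(is.na(r)))))
    poses[!valid, ] <- NA_real_
  df <- data.frame(frame = seq_along(time), time = time,
                   tx = poses[, 1], ty = poses[, 2], tz = poses[, 3],
                   pitch = poses[, 4], yaw = poses[, 5], roll = poses[, 6],
                   valid = valid, methods = methods,
                   stringsAsFactors = FALSE)
  class(df) <- c("pose_trace", "data.frame")
  df
}

#' @export
print.pose_trace <- function(x, ...) {
  cat(sprintf("pose trace: %d frames (%d valid), %.2f s\n",
              nrow(x), sum(x$valid), diff(range(x$time))))
  NextMethod()
}

#' Plot a pose trace
#'
#' Six stacked panels, one per DOF, in the layout conventional for
#' head-tracking time series.
#'
#' @param x a [pose_trace()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.pose_trace <- function(x, ...) {
  dof <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  unit <- c(rep("mm", 3), rep("deg", 3))
  old <- graphics::par(mfrow = c(6, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (k in seq_along(dof)) {
    graphics::plot(x$time, x[[dof[k]]], type = "l",
                   xlab = "time (s)", ylab = paste0(dof[k], " (", unit[k], ")"),
                   ...)
  }
  invisible(x)
}

trace_schema <- "moirepose/pose_trace/1"

#' Read and write pose-trace CSV files
#'
#' Lossless CSV round trip of a [pose_trace()], including validity flags
#' and method tags. A schema comment line stamps the file version.
#'
#' @param trace a \code{pose_trace}.
#' @param path file path.
#' @return \code{read_pose_trace} returns a \code{pose_trace}.
#' @export
write_pose_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", trace_schema), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_trace
#' @export
read_pose_trace <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#") || !grepl("pose_trace", first))
    stop("read_pose_trace: ", path, " is not a pose-trace file (missing schema header)")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "time", "tx", "ty", "tz", "pitch", "yaw", "roll", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_pose_trace: missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("read_pose_trace: empty trace in ", path)
  if (is.null(df$methods)) df$methods <- ""
  df$methods[is.na(df$methods)] <- ""
  pose_trace(df$time, as.matrix(df[, c("tx", "ty", "tz", "pitch", "yaw", "roll")]),
             valid = df$valid, methods = df$methods)
}

#' Read and write stereo-rig calibration JSON
#'
#' Serialises intrinsics (with distortion) of both cameras and the
#' extrinsic right-to-left transform (4x4 row-major) plus its 6-DOF
#' decomposition.
#'
#' @param rig a [stereo_rig()].
#' @param path file path.
#' @return \code{read_rig_json} returns a \code{stereo_rig} (without
#'   world mounts, which are a rendering concept).
#' @export
write_rig_json <- function(rig, path) {
  cam_list <- function(cam) list(fx = cam$fx, fy = cam$fy, cx = cam$cx,
                                 cy = cam$cy, distortion = cam$distortion,
                                 resolution = cam$resolution)
  E <- rig$extrinsic
  M <- rbind(cbind(E$R, E$t), c(0, 0, 0, 1))
  x <- list(schema = "moirepose/rig/1",
            left = cam_list(rig$left), right = cam_list(rig$right),
            extrinsic_right_to_left = as.numeric(t(M)),
            extrinsic_6dof = as.list(unclass(transform_to_pose(E))[1:6]))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rig_json
#' @export
read_rig_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "moirepose/rig/1"))
    stop("read_rig_json: unrecognised schema in ", path)
  mk <- function(c) camera_intrinsics(c$fx, c$fy, c$cx, c$cy,
                                      distortion = c$distortion,
                                      resolution = c$resolution)
  M <- matrix(x$extrinsic_right_to_left, 4, byrow = TRUE)
  stereo_rig(mk(x$left), mk(x$right),
             rigid_transform(M[1:3, 1:3], M[1:3, 4]))
}

#' Read and write grayscale PNG frames
#'
#' Frames are stored as 8-bit grayscale PNG; a directory of frames named
#' \code{frame_000001.png, ...} forms a stream.
#'
#' @param frame a [new_frame()].
#' @param path file path.
#' @param timestamp,camera_id metadata attached on read.
#' @return \code{read_frame_png} returns a \code{frame}.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame$pixels / 255, path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path, timestamp = 0, camera_id = "cam") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    # ITU-R 601 luma for colour input
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  new_frame(a * 255, timestamp = timestamp, camera_id = camera_id)
}

#' Read a directory of PNG frames
#'
#' @param dir directory containing PNG frames (lexicographic order).
#' @param fps frame rate used to assign timestamps.
#' @param camera_id camera label.
#' @return list of [new_frame()] objects.
#' @export
read_frame_dir <- function(dir, fps = 30, camera_id = "cam") {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("read_frame_dir: no PNG frames in ", dir)
  lapply(seq_along(files), function(i)
    read_frame_png(files[i], timestamp = (i - 1) / fps,
                   camera_id = camera_id))
}

#' Export per-frame moire analysis results as CSV
#'
#' One row per analysed frame: the four fitted grating phases (radians)
#' and the occlusion flag; occluded frames carry NA phases.
#'
#' @param analyses list of [analyze_marker_frame()] results.
#' @param path output CSV path.
#' @param camera_id camera label recorded in the rows.
#' @return the written data.frame, invisibly.
#' @export
write_analysis_csv <- function(analyses, path, camera_id = "cam") {
  get_phase <- function(a, g) {
    if (a$occluded || is.null(a$phases[[g]])) NA_real_
    else a$phases[[g]]$phase
  }
  df <- data.frame(
    frame_index = seq_along(analyses),
    camera_id = camera_id,
    phase_fine_pitch = vapply(analyses, get_phase, 0, g = "pitch_fine"),
    phase_coarse_pitch = vapply(analyses, get_phase, 0, g = "pitch_coarse"),
    phase_fine_yaw = vapply(analyses, get_phase, 0, g = "yaw_fine"),
    phase_coarse_yaw = vapply(analyses, get_phase, 0, g = "yaw_coarse"),
    occluded = vapply(analyses, `[[`, TRUE, "occluded"))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a calibration report
#'
#' Serialises an [estimate_intrinsics()] result (plus optionally the
#' stereo extrinsics) as JSON: intrinsics with distortion, per-view and
#' mean reprojection errors, and the extrinsic transform.
#'
#' @param fit result of [estimate_intrinsics()].
#' @param path output JSON path.
#' @param stereo optional result of [estimate_stereo_extrinsics()].
#' @export
write_calibration_report <- function(fit, path, stereo = NULL) {
  cam <- fit$intrinsics
  x <- list(schema = "moirepose/calibration_report/1",
            intrinsics = list(fx = cam$fx, fy = cam$fy, cx = cam$cx,
                              cy = cam$cy, distortion = cam$distortion,
                              resolution = cam$resolution),
            reproj_rms_mean = fit$reproj_rms,
            reproj_rms_per_view = fit$per_view_rms)
  if (!is.null(stereo)) {
    E <- stereo$extrinsic
    x$extrinsic <- list(
      matrix_4x4_row_major = as.numeric(t(rbind(cbind(E$R, E$t),
                                                c(0, 0, 0, 1)))),
      pose_6dof = as.list(unclass(transform_to_pose(E))[1:6]),
      reproj_rms = stereo$reproj_rms,
      baseline_mm = stereo$baseline)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records seeds, package version and a digest of the configuration next
#' to any batch output, so a run can be reproduced.
#'
#' @param path output JSON path.
#' @param seed seed(s) used.
#' @param config any serialisable configuration list.
#' @export
write_run_manifest <- function(path, seed, config = list()) {
  x <- list(schema = "moirepose/manifest/1",
            package_version = as.character(utils::packageVersion("moirepose")),
            r_version = R.version.string,
            seed = seed,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            config = config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
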