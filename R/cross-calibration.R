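# Rigid cross-calibration between the optical-tracking and scanner
# coordinate systems from matched point pairs.

#' Cross-calibration phantom specification
#'
#' A rigid phantom carrying 15 scanner-visible wells (fluid-filled,
#' arranged as a 5 x 3 grid) and 15 camera-visible square fiducials
#' mounted directly above them with a fixed depth offset. Any 3
#' non-collinear point pairs suffice to solve the transform, so losing
#' some of the 15 redundant points to occlusion is acceptable.
#'
#' @param nx,ny grid counts (nx * ny = 15 by default).
#' @param spacing grid spacing (mm).
#' @param depth_offset vertical offset from well bottom to fiducial (mm).
#' @return object of class \code{phantom_spec} with \code{wells} and
#'   \code{fiducials} (15 x 3 matrices, phantom frame) and labels.
#' @export
phantom_spec <- function(nx = 5, ny = 3, spacing = 30, depth_offset = 20) {
  g <- expand.grid(x = (seq_len(nx) - (nx + 1) / 2) * spacing,
                   y = (seq_len(ny) - (ny + 1) / 2) * spacing)
  wells <- cbind(g$x, g$y, 0)
  fid <- cbind(g$x, g$y, depth_offset)
  structure(list(wells = wells, fiducials = fid,
                 labels = sprintf("P%02d", seq_len(nrow(wells))),
                 depth_offset = depth_offset),
            class = "phantom_spec")
}

#' Matched point correspondences
#'
#' @param source n x 3 points in the source (camera) frame (mm).
#' @param target n x 3 points in the target (scanner) frame (mm).
#' @param labels optional point labels; correspondences are matched by
#'   position after sorting both sets by label.
#' @return object of class \code{point_correspondences}.
#' @export
point_correspondences <- function(source, target, labels = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3, ncol(target) == 3,
            nrow(source) == nrow(target))
  if (nrow(source) < 3)
    stop("point_correspondences: at least 3 point pairs required")
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(source))
    o <- order(labels)
    source <- source[o, , drop = FALSE]
    target <- target[o, , drop = FALSE]
    labels <- labels[o]
  }
  structure(list(source = source, target = target, labels = labels),
            class = "point_correspondences")
}

#' Camera-point preprocessing for cross-calibration
#'
#' Applies the documented gross coordinate adjustments to raw camera
#' points seen via the in-bore mirror, before the rigid transform is
#' solved: (1) the mirror fold, a -90 degree rotation about X; (2) the
#' frame-convention flips, 180 degree rotations about X then Z; (3) a
#' -3000 mm offset in Z (the approximate camera-to-isocentre distance).
#' Removing these large, approximately-known discrepancies first leaves
#' only a small residual transform for the SVD solve, improving its
#' numerical stability. Each step can be toggled; the exact residual is
#' absorbed by the solved transform either way.
#'
#' @param points n x 3 camera points (mm).
#' @param mirror_fold apply the -90 degree X rotation.
#' @param frame_convention apply the 180 degree X and Z rotations.
#' @param z_offset Z translation (mm); set to 0 to disable.
#' @return n x 3 preprocessed points.
#' @export
preprocess_camera_points <- function(points, mirror_fold = TRUE,
                                     frame_convention = TRUE,
                                     z_offset = -3000) {
  p <- as.matrix(points)
  if (mirror_fold)
    p <- p %*% t(euler_to_matrix(pitch = -90))
  if (frame_convention) {
    p <- p %*% t(euler_to_matrix(pitch = 180))
    p <- p %*% t(euler_to_matrix(roll = 180))
  }
  p[, 3] <- p[, 3] + z_offset
  p
}

#' Inverse of the camera-point preprocessing
#'
#' @inheritParams preprocess_camera_points
#' @export
unpreprocess_camera_points <- function(points, mirror_fold = TRUE,
                                       frame_convention = TRUE,
                                       z_offset = -3000) {
  p <- as.matrix(points)
  p[, 3] <- p[, 3] - z_offset
  if (frame_convention) {
    p <- p %*% t(euler_to_matrix(roll = -180))
    p <- p %*% t(euler_to_matrix(pitch = -180))
  }
  if (mirror_fold)
    p <- p %*% t(euler_to_matrix(pitch = 90))
  p
}

#' Solve the rigid transform between matched point sets
#'
#' Kabsch/Umeyama rigid registration without scaling: both sets are
#' centred, the 3 x 3 cross-covariance is decomposed by SVD, the rotation
#' sign is corrected so det(R) = +1 (never a reflection), and the
#' translation follows from the centroids. The result minimises the sum
#' of squared pair distances. The fiducial registration error (FRE) is
#' reported as the RMS residual distance over pairs.
#'
#' @param corr a [point_correspondences()] (or a list with \code{source}
#'   and \code{target} matrices).
#' @return list with \code{transform} (a [rigid_transform()] mapping
#'   source to target), \code{fre} (mm) and \code{residuals} (per-pair
#'   distances, mm).
#' @export
solve_rigid_transform <- function(corr) {
  src <- as.matrix(corr$source); tgt <- as.matrix(corr$target)
  n <- nrow(src)
  if (n < 3) stop("solve_rigid_transform: at least 3 pairs required")
  cs <- colMeans(src); ct <- colMeans(tgt)
  A <- sweep(src, 2, cs); B <- sweep(tgt, 2, ct)
  # collinearity check on the source cloud
  if (svd(A)$d[2] < 1e-9 * max(svd(A)$d[1], 1))
    stop("solve_rigid_transform: degenerate (collinear) point set")
  H <- crossprod(A, B)                  # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- ct - drop(R %*% cs)
  tf <- rigid_transform(R, t)
  res <- sqrt(rowSums((apply_transform(tf, src) - tgt)^2))
  list(transform = tf, fre = sqrt(mean(res^2)), residuals = res)
}

#' Repeatability of repeated cross-calibrations
#'
#' Decomposes each trial transform into 6 DOF (package Euler convention)
#' and reports, per DOF, the mean, standard deviation, and the maximum
#' absolute deviation from the across-trial mean -- the repeatability
#' figure used to judge whether cross-calibration stays within the
#' 1 mm / 1 degree budget for motion correction.
#'
#' @param trials list of [rigid_transform()]s (>= 2).
#' @return data.frame with rows tx, ty, tz (mm), pitch, yaw, roll (deg)
#'   and columns \code{mean}, \code{sd}, \code{max_dev}.
#' @export
repeatability <- function(trials) {
  if (length(trials) < 2)
    stop("repeatability: at least 2 trials required")
  P <- t(vapply(trials, function(tf) unclass(transform_to_pose(tf))[1:6],
                numeric(6)))
  colnames(P) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  m <- colMeans(P)
  dev <- abs(sweep(P, 2, m))
  data.frame(mean = m,
             sd = apply(P, 2, sd),
             max_dev = apply(dev, 2, max),
             row.names = colnames(P))
}
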