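#' Camera intrinsics
#'
#' Pinhole camera model with radial-tangential lens distortion
#' (k1, k2, p1, p2, k3), the standard model used by planar calibration
#' toolchains.
#'
#' @param fx,fy focal lengths (px).
#' @param cx,cy principal point (px).
#' @param distortion length-5 numeric (k1, k2, p1, p2, k3).
#' @param resolution image size \code{c(width, height)} in px.
#' @return object of class \code{camera_intrinsics}.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy,
                              distortion = c(0, 0, 0, 0, 0),
                              resolution = c(720, 480)) {
  stopifnot(fx > 0, fy > 0, length(distortion) == 5)
  if (cx <= 0 || cx >= resolution[1] || cy <= 0 || cy >= resolution[2])
    stop("camera_intrinsics: principal point must lie inside the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 distortion = as.numeric(distortion),
                 resolution = as.numeric(resolution)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Camera intrinsics: fx=%.5g fy=%.5g c=(%.4g, %.4g) %gx%g px\n",
              x$fx, x$fy, x$cx, x$cy, x$resolution[1], x$resolution[2]))
  if (any(x$distortion != 0))
    cat("  distortion:", paste(signif(x$distortion, 4), collapse = " "), "\n")
  invisible(x)
}

#' Camera presets of the tracking platform
#'
#' \code{"external"}: the remote marker-tracking cameras -- 720 x 480 px,
#' 76 x 58 mm field of view at a 3 m working distance (200 mm-equivalent
#' lens, FOV about 1.5 degrees). \code{"inbore"}: the in-bore head
#' cameras -- 720 x 480 px, 151 x 112 mm field of view at about a 220 mm
#' working distance (6 mm lens).
#'
#' @param preset \code{"external"} or \code{"inbore"}.
#' @return a [camera_intrinsics()].
#' @export
camera_preset <- function(preset = c("external", "inbore")) {
  preset <- match.arg(preset)
  if (preset == "external") {
    d <- 3000
    camera_intrinsics(fx = 720 * d / 76, fy = 480 * d / 58,
                      cx = 360, cy = 240)
  } else {
    d <- 220
    camera_intrinsics(fx = 720 * d / 151, fy = 480 * d / 112,
                      cx = 360, cy = 240)
  }
}

# intrinsic matrix
K_matrix <- function(cam) {
  matrix(c(cam$fx, 0, cam$cx, 0, cam$fy, cam$cy, 0, 0, 1), 3, byrow = TRUE)
}

# apply radial-tangential distortion to normalized coords (n x 2)
distort_normalized <- function(xy, dist) {
  x <- xy[, 1]; y <- xy[, 2]
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  r2 <- x^2 + y^2
  rad <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  cbind(xd, yd)
}

# invert distortion by fixed-point iteration on normalized coords
undistort_normalized <- function(xy, dist, iters = 8) {
  if (all(dist == 0)) return(xy)
  u <- xy
  for (i in seq_len(iters)) {
    d <- distort_normalized(u, dist) - u
    u <- xy - d
  }
  u
}

#' Convert pixel points to undistorted normalized coordinates (and back)
#'
#' @param pts n x 2 pixel coordinates.
#' @param cam a [camera_intrinsics()].
#' @return n x 2 matrix.
#' @export
undistort_points <- function(pts, cam) {
  xy <- cbind((pts[, 1] - cam$cx) / cam$fx, (pts[, 2] - cam$cy) / cam$fy)
  undistort_normalized(xy, cam$distortion)
}

# project camera-frame 3-D points to pixels (applying distortion)
project_camera_points <- function(X, cam) {
  xy <- cbind(X[, 1] / X[, 3], X[, 2] / X[, 3])
  xyd <- distort_normalized(xy, cam$distortion)
  cbind(cam$fx * xyd[, 1] + cam$cx, cam$fy * xyd[, 2] + cam$cy)
}

#' Project world points through a camera
#'
#' @param X n x 3 world points (mm).
#' @param cam a [camera_intrinsics()].
#' @param view a [rigid_transform()] mapping world to camera coordinates.
#' @return n x 2 pixel coordinates.
#' @export
project_points <- function(X, cam, view) {
  project_camera_points(apply_transform(view, X), cam)
}

#' Camera mounting "look-at" transform
#'
#' Builds the world-to-camera rigid transform for a camera at world
#' position \code{center} whose optical axis points at \code{target},
#' with the image x axis aligned with world \code{up} x axis convention
#' (image y runs down).
#'
#' @param center,target world points (mm).
#' @param up world up direction.
#' @return a [rigid_transform()] (world -> camera).
#' @export
camera_look_at <- function(center, target = c(0, 0, 0), up = c(0, 1, 0)) {
  z <- target - center; z <- z / sqrt(sum(z^2))
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])          # z cross up
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])            # z cross x
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  rigid_transform(R, -drop(R %*% center))
}

#' Stereo rig
#'
#' Two calibrated cameras with a rigid extrinsic relation. The extrinsic
#' transform maps right-camera coordinates into the left-camera frame
#' (\code{X_left = R X_right + t}); the left camera is the origin of the
#' rig. Optional mounting transforms (world -> camera) position the rig
#' in the world frame for rendering.
#'
#' @param left,right [camera_intrinsics()] for the two cameras.
#' @param extrinsic [rigid_transform()] right -> left.
#' @param mount_left,mount_right optional world -> camera transforms.
#' @return object of class \code{stereo_rig}.
#' @export
stereo_rig <- function(left, right, extrinsic,
                       mount_left = NULL, mount_right = NULL) {
  b <- sqrt(sum(extrinsic$t^2))
  if (b <= 0) stop("stereo_rig: baseline must be positive")
  structure(list(left = left, right = right, extrinsic = extrinsic,
                 baseline = b,
                 mount_left = mount_left, mount_right = mount_right),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("Stereo rig: baseline %.4g mm\n", x$baseline))
  print(transform_to_pose(x$extrinsic, frame_id = "right->left"))
  invisible(x)
}

#' Benchtop/in-bore stereo rig preset
#'
#' Two external-preset cameras separated by \code{baseline} on a wall at
#' \code{distance} from the marker, both toed in to view the marker
#' (about 11 degrees of relative yaw at the default 600 mm / 3 m
#' geometry). World frame = reference marker frame (marker at origin,
#' Z towards the cameras).
#'
#' @param baseline camera separation (mm).
#' @param distance wall-to-marker distance (mm).
#' @param camera intrinsics used for both cameras.
#' @return a [stereo_rig()].
#' @export
stereo_rig_preset <- function(baseline = 600, distance = 3000,
                              camera = camera_preset("external")) {
  cl <- c(baseline / 2, 0, distance)
  cr <- c(-baseline / 2, 0, distance)
  ml <- camera_look_at(cl)
  mr <- camera_look_at(cr)
  # X_l = Ml(x_w), X_r = Mr(x_w)  =>  X_l = (Ml o Mr^-1)(X_r)
  ext <- compose_transform(ml, invert_transform(mr))
  stereo_rig(camera, camera, ext, mount_left = ml, mount_right = mr)
}

#' Triangulate stereo point correspondences
#'
#' Linear (direct linear transform) triangulation of matched pixel
#' points observed by the two cameras of a rig. Points are undistorted,
#' then each 3-D point is recovered as the least-squares solution of the
#' homogeneous DLT system via SVD, expressed in the left-camera frame.
#'
#' @param left_pts,right_pts n x 2 pixel coordinates (matched order).
#' @param rig a [stereo_rig()].
#' @param min_angle_deg minimum ray separation; near-parallel ray pairs
#'   below this angle are an error (depth unobservable).
#' @return n x 3 matrix of points (mm, left-camera frame).
#' @export
triangulate_points <- function(left_pts, right_pts, rig, min_angle_deg = 0.1) {
  xl <- undistort_points(left_pts, rig$left)
  xr <- undistort_points(right_pts, rig$right)
  # normalized projection matrices: left [I|0], right [R'| -R't]
  E <- rig$extrinsic
  Rr <- t(E$R); tr <- -drop(t(E$R) %*% E$t)
  P2 <- cbind(Rr, tr)
  n <- nrow(xl)
  out <- matrix(NA_real_, n, 3)
  P1 <- cbind(diag(3), c(0, 0, 0))
  for (i in seq_len(n)) {
    A <- rbind(
      P1[3, ] * xl[i, 1] - P1[1, ],
      P1[3, ] * xl[i, 2] - P1[2, ],
      P2[3, ] * xr[i, 1] - P2[1, ],
      P2[3, ] * xr[i, 2] - P2[2, ]
    )
    s <- svd(A)
    X <- s$v[, 4]
    out[i, ] <- X[1:3] / X[4]
    # ray-angle conditioning check
    d1 <- c(xl[i, ], 1)
    d2 <- drop(t(Rr) %*% c(xr[i, ], 1))
    ang <- acos(min(1, abs(sum(d1 * d2)) / sqrt(sum(d1^2) * sum(d2^2))))
    if (ang * 180 / pi < min_angle_deg)
      stop("triangulate_points: near-parallel rays (conditioning)")
  }
  out
}
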