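#' Rotation matrix from Euler angles
#'
#' Builds the 3x3 rotation matrix for intrinsic rotations applied in the
#' order roll (about Z), yaw (about Y), pitch (about X):
#' \code{R = Rz(roll) Ry(yaw) Rx(pitch)}. This convention is fixed across
#' the package; at the sub-2-degree amplitudes typical of head motion the
#' ordering effect is below 0.01 degrees, but it matters for reporting.
#'
#' @param pitch,yaw,roll angles in degrees.
#' @return 3x3 orthonormal rotation matrix.
#' @export
euler_to_matrix <- function(pitch = 0, yaw = 0, roll = 0) {
  p <- pitch * pi / 180; y <- yaw * pi / 180; r <- roll * pi / 180
  cx <- cos(p); sx <- sin(p)
  cy <- cos(y); sy <- sin(y)
  cz <- cos(r); sz <- sin(r)
  matrix(c(
    cz * cy, cz * sy * sx - sz * cx, sz * sx + cz * sy * cx,
    sz * cy, cz * cx + sz * sy * sx, sz * sy * cx - cz * sx,
    -sy,     cy * sx,                cy * cx
  ), nrow = 3, byrow = TRUE)
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. The principal branch is returned
#' (yaw in \[-90, 90\] degrees); gimbal lock at |yaw| = 90 degrees is
#' resolved by assigning the in-plane angle to roll.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector \code{c(pitch, yaw, roll)} in degrees.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  yaw <- asin(sy)
  if (abs(sy) < 1 - 1e-12) {
    pitch <- atan2(R[3, 2], R[3, 3])
    roll <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: pitch and roll degenerate; put everything in roll
    pitch <- 0
    roll <- atan2(-R[1, 2], R[2, 2])
  }
  c(pitch = pitch, yaw = yaw, roll = roll) * 180 / pi
}

#' 6-DOF pose
#'
#' A rigid pose: translations in millimetres and rotations in degrees
#' (pitch about X, yaw about Y, roll about Z; see [euler_to_matrix()] for
#' the composition order).
#'
#' @param tx,ty,tz translations (mm).
#' @param pitch,yaw,roll rotations (degrees).
#' @param frame_id optional label of the coordinate frame.
#' @return object of class \code{pose6dof}: a named numeric vector of
#'   length 6 with attribute \code{frame_id}.
#' @export
pose6dof <- function(tx = 0, ty = 0, tz = 0, pitch = 0, yaw = 0, roll = 0,
                     frame_id = "marker") {
  v <- c(tx = tx, ty = ty, tz = tz, pitch = pitch, yaw = yaw, roll = roll)
  if (!all(is.finite(v))) stop("pose6dof: all components must be finite")
  structure(v, frame_id = frame_id, class = "pose6dof")
}

#' @export
print.pose6dof <- function(x, ...) {
  cat(sprintf(
    "6-DOF pose [%s]: t = (%.4g, %.4g, %.4g) mm, (pitch, yaw, roll) = (%.4g, %.4g, %.4g) deg\n",
    attr(x, "frame_id") %||% "?", x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rigid transform
#'
#' Rotation plus translation mapping points from one frame to another:
#' \code{y = R x + t}.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation (mm).
#' @return object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R); t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("rigid_transform: R must be orthonormal with det +1")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  d <- transform_to_pose(x)
  cat("Rigid transform:\n")
  print(unclass(d))
  invisible(x)
}

#' Convert a 6-DOF pose to a rigid transform (and back)
#'
#' \code{pose_to_transform} builds \code{y = R x + t} with
#' \code{R = euler_to_matrix(pitch, yaw, roll)} and \code{t = (tx,ty,tz)};
#' \code{transform_to_pose} decomposes a transform back into 6 DOF using
#' the package Euler convention.
#'
#' @param pose a [pose6dof()].
#' @param tf a [rigid_transform()].
#' @param frame_id frame label for the decomposed pose.
#' @return a \code{rigid_transform} / \code{pose6dof} respectively.
#' @export
pose_to_transform <- function(pose) {
  rigid_transform(euler_to_matrix(pose[["pitch"]], pose[["yaw"]], pose[["roll"]]),
                  c(pose[["tx"]], pose[["ty"]], pose[["tz"]]))
}

#' @rdname pose_to_transform
#' @export
transform_to_pose <- function(tf, frame_id = "marker") {
  e <- matrix_to_euler(tf$R)
  pose6dof(tf$t[1], tf$t[2], tf$t[3], e[["pitch"]], e[["yaw"]], e[["roll"]],
           frame_id = frame_id)
}

#' Apply, invert and compose rigid transforms
#'
#' \code{apply_transform} maps points (an N x 3 matrix, a length-3 vector,
#' or a \code{pose6dof}, in which case the pose's transform is conjugated);
#' \code{invert_transform} returns the inverse; \code{compose_transform}
#' returns \code{a} after \code{b} (i.e. \code{x -> a(b(x))}).
#'
#' @param tf,a,b rigid transforms.
#' @param x points or pose to transform.
#' @return transformed points (same shape as input) or a transform.
#' @export
apply_transform <- function(tf, x) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "pose6dof")) {
    composed <- compose_transform(tf, pose_to_transform(x))
    return(transform_to_pose(composed, frame_id = attr(x, "frame_id")))
  }
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    return(drop(tf$R %*% x + tf$t))
  }
  stopifnot(ncol(x) == 3)
  sweep(x %*% t(tf$R), 2, -tf$t)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), -drop(t(tf$R) %*% tf$t))
}

#' @rdname apply_transform
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, drop(a$R %*% b$t) + a$t)
}

# wrap angle(s) in radians to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
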