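# Homography estimation and planar perspective-n-point pose.

#' Estimate a homography from point correspondences
#'
#' Normalized direct linear transform: both point sets are translated and
#' scaled to mean distance sqrt(2) from the origin, the 2n x 9 DLT system
#' is solved by SVD, and the normalisations are undone. At least four
#' correspondences are required; a degenerate (e.g. collinear) geometry
#' raises an error via a conditioning check.
#'
#' @param src,dst n x 2 matrices of corresponding points.
#' @return 3 x 3 homography H with \code{dst ~ H src} (unit H33 scale).
#' @export
estimate_homography <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 4)
  norm_pts <- function(p) {
    m <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, m)^2))
    s <- sqrt(2) / mean(d)
    T <- matrix(c(s, 0, -s * m[1], 0, s, -s * m[2], 0, 0, 1), 3, byrow = TRUE)
    list(T = T, p = cbind(s * (p[, 1] - m[1]), s * (p[, 2] - m[2])))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  n <- length(x)
  z <- rep(0, n); o <- rep(1, n)
  A <- rbind(
    cbind(-x, -y, -o, z, z, z, u * x, u * y, u),
    cbind(z, z, z, -x, -y, -o, v * x, v * y, v)
  )
  s <- svd(A, nu = 0, nv = 9)
  if (s$d[8] / s$d[1] < 1e-10)
    stop("estimate_homography: degenerate point configuration")
  H <- matrix(s$v[, 9], 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

# map points through a homography (n x 2 -> n x 2)
apply_homography <- function(H, p) {
  q <- cbind(p, 1) %*% t(H)
  cbind(q[, 1] / q[, 3], q[, 2] / q[, 3])
}

# decompose a plane-to-normalized-image homography into R, t
# (object plane Z = 0; H maps (X, Y) mm -> normalized image coords)
homography_to_pose <- function(H) {
  h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
  lam <- 2 / (sqrt(sum(h1^2)) + sqrt(sum(h2^2)))
  r1 <- h1 * lam; r2 <- h2 * lam; t <- h3 * lam
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t }
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  R <- cbind(r1, r2, r3)
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  dimnames(R) <- NULL
  list(R = R, t = t)
}

# axis-angle to rotation matrix (Rodrigues)
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew(w))
  k <- w / th
  K <- skew(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

skew <- function(v) {
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, byrow = TRUE)
}

#' Planar perspective-n-point pose
#'
#' Estimates the full 6-DOF rigid transform from a planar object (marker
#' checkerboard, Z = 0 in the object frame) to the camera, from detected
#' pixel corners. The solution is initialised from the decomposition of
#' the object-plane homography (the standard route for planar targets)
#' and refined by Gauss-Newton iterations on the pixel reprojection
#' error.
#'
#' Only the in-plane components (tx, ty and roll about the optical axis)
#' are reliable with a single narrow-field camera; through-plane
#' components are returned but flagged, since monocular planar PnP is
#' known to be unstable in depth and tilt under a narrow field of view.
#'
#' @param corners n x 2 detected pixel points (n >= 6).
#' @param object_pts n x 3 matching object-frame points (Z = 0, mm), e.g.
#'   from [checkerboard_corners()].
#' @param cam a [camera_intrinsics()].
#' @param refine_iters Gauss-Newton iterations.
#' @return list with \code{transform} (object -> camera
#'   [rigid_transform()]), \code{reproj_rms} (px) and
#'   \code{reliable = c("tx", "ty", "roll")}.
#' @export
solve_planar_pnp <- function(corners, object_pts, cam, refine_iters = 10) {
  stopifnot(nrow(corners) >= 6, nrow(corners) == nrow(object_pts))
  if (max(abs(object_pts[, 3])) > 1e-9)
    stop("solve_planar_pnp: object points must lie in the Z = 0 plane")
  xy <- undistort_points(corners, cam)
  H <- estimate_homography(object_pts[, 1:2, drop = FALSE], xy)
  p0 <- homography_to_pose(H)
  R <- p0$R; t <- p0$t
  obj <- as.matrix(object_pts)
  target <- as.numeric(t(corners))
  # Gauss-Newton on (w, t) with R <- rodrigues(w) R_cur composition
  for (it in seq_len(refine_iters)) {
    cur <- rigid_transform(R, t)
    proj <- project_points(obj, cam, cur)
    r <- as.numeric(t(proj)) - target
    J <- matrix(0, length(r), 6)
    eps <- 1e-6
    for (k in 1:3) {
      w <- c(0, 0, 0); w[k] <- eps
      pr <- project_points(obj, cam, rigid_transform(rodrigues(w) %*% R, t))
      J[, k] <- (as.numeric(t(pr)) - target - r) / eps
    }
    for (k in 1:3) {
      t2 <- t; t2[k] <- t2[k] + eps
      pr <- project_points(obj, cam, rigid_transform(R, t2))
      J[, 3 + k] <- (as.numeric(t(pr)) - target - r) / eps
    }
    delta <- tryCatch(solve(crossprod(J) + 1e-9 * diag(6), -crossprod(J, r)),
                      error = function(e) NULL)
    if (is.null(delta)) break
    R <- rodrigues(delta[1:3]) %*% R
    t <- t + delta[4:6]
    if (max(abs(delta)) < 1e-10) break
  }
  tf <- rigid_transform(R, t)
  proj <- project_points(obj, cam, tf)
  rms <- sqrt(mean((proj - corners)^2) * 2)
  list(transform = tf, reproj_rms = rms, reliable = c("tx", "ty", "roll"))
}

#' Relative marker pose from two PnP solutions
#'
#' Expresses the displacement of the marker between a reference and a
#' current view in the reference marker frame:
#' \code{D = T_ref^-1 o T_cur}, decomposed into 6 DOF.
#'
#' @param ref,cur object -> camera transforms from [solve_planar_pnp()].
#' @return a [pose6dof()] (displacement in the reference marker frame).
#' @export
relative_marker_pose <- function(ref, cur) {
  transform_to_pose(compose_transform(invert_transform(ref), cur))
}
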