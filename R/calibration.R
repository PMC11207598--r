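# Camera calibration: placement protocol, planar (Zhang-style) intrinsic
# estimation with bundle refinement, and stereo extrinsic estimation.

#' Calibration board specification
#'
#' A plain black and white checkerboard used for calibration; the default
#' is 10 x 15 squares of 3 mm (9 x 14 inner corners). Unequal side counts
#' are recommended so the board orientation is unambiguous.
#'
#' @param rows,cols square counts.
#' @param square square edge (mm).
#' @return object of class \code{calibration_board_spec}.
#' @export
calibration_board_spec <- function(rows = 10, cols = 15, square = 3) {
  stopifnot(rows >= 3, cols >= 3, square > 0)
  structure(list(rows = rows, cols = cols, square = square),
            class = "calibration_board_spec")
}

#' Inner corners of a calibration board
#'
#' @param board a [calibration_board_spec()].
#' @return (rows-1)(cols-1) x 3 matrix (mm, board frame, Z = 0), row-major
#'   from the top-left inner corner.
#' @export
calibration_board_corners <- function(board) {
  w <- board$cols * board$square; h <- board$rows * board$square
  xs <- -w / 2 + board$square * seq_len(board$cols - 1)
  ys <- h / 2 - board$square * seq_len(board$rows - 1)
  g <- expand.grid(x = xs, y = ys)
  cbind(g$x, g$y, 0)
}

#' The 50-placement calibration protocol
#'
#' Enumerates the image-collection protocol used to calibrate the
#' long-focal-length tracking cameras: the field of view is partitioned
#' into an overlapping 3 x 3 grid; the board visits the nine cells in
#' reading order collecting five images each (forward, tilt left, right,
#' up, down), then four more at the centre with compound tilts (top-left,
#' top-right, bottom-left, bottom-right) and one final forward centre
#' image -- 50 placements in total. The output is deterministic and
#' order-stable.
#'
#' @return data.frame with columns \code{position} (1..50),
#'   \code{grid_cell} and \code{tilt}.
#' @export
generate_calibration_protocol <- function() {
  cells <- c("top-left", "top-centre", "top-right",
             "middle-left", "centre", "middle-right",
             "bottom-left", "bottom-centre", "bottom-right")
  tilts <- c("none", "left", "right", "up", "down")
  base <- data.frame(grid_cell = rep(cells, each = length(tilts)),
                     tilt = rep(tilts, times = length(cells)),
                     stringsAsFactors = FALSE)
  extra <- data.frame(grid_cell = "centre",
                      tilt = c("top-left", "top-right",
                               "bottom-left", "bottom-right", "none"),
                      stringsAsFactors = FALSE)
  out <- rbind(base, extra)
  out <- cbind(position = seq_len(nrow(out)), out)
  out
}

# board pose (board -> world/camera-wall frame) for one protocol entry
protocol_board_pose <- function(grid_cell, tilt, distance = 0,
                                cell_step = c(15, 12), tilt_deg = 12) {
  gx <- switch(sub("-.*", "", grid_cell),
               "top" = 1, "middle" = 0, "bottom" = -1, "centre" = 0)
  # horizontal part of the cell name
  hx <- if (grepl("left", grid_cell)) -1 else if (grepl("right", grid_cell)) 1 else 0
  ty <- gx * cell_step[2]
  tx <- hx * cell_step[1]
  ang <- switch(tilt,
    "none" = c(0, 0), "left" = c(0, -tilt_deg), "right" = c(0, tilt_deg),
    "up" = c(tilt_deg, 0), "down" = c(-tilt_deg, 0),
    "top-left" = c(tilt_deg, -tilt_deg), "top-right" = c(tilt_deg, tilt_deg),
    "bottom-left" = c(-tilt_deg, -tilt_deg),
    "bottom-right" = c(-tilt_deg, tilt_deg))
  rigid_transform(euler_to_matrix(pitch = ang[1], yaw = ang[2]),
                  c(tx, ty, distance))
}

#' Simulate calibration observations
#'
#' Generates per-view detected-corner sets for the placement protocol by
#' projecting a calibration board through known ("ground truth") cameras,
#' optionally with Gaussian corner noise. World frame: board at the
#' camera focus depth, cameras on the rig mounts (or a single camera at
#' its preset working distance).
#'
#' @param board a [calibration_board_spec()].
#' @param cam a [camera_intrinsics()] (monocular) -- or a [stereo_rig()]
#'   with mounts for paired views.
#' @param protocol data.frame from [generate_calibration_protocol()].
#' @param noise_sd corner noise (px).
#' @param seed RNG seed.
#' @param tilt_deg board tilt magnitude (degrees).
#' @return list of views; each view has \code{corners} (monocular) or
#'   \code{left}/\code{right} matrices, plus the true \code{pose}.
#' @export
simulate_calibration_views <- function(board, cam,
                                       protocol = generate_calibration_protocol(),
                                       noise_sd = 0, seed = 1,
                                       tilt_deg = 12) {
  set.seed(seed)
  pts <- calibration_board_corners(board)
  stereo <- inherits(cam, "stereo_rig")
  lapply(seq_len(nrow(protocol)), function(i) {
    pose <- protocol_board_pose(protocol$grid_cell[i], protocol$tilt[i],
                                tilt_deg = tilt_deg)
    Xw <- apply_transform(pose, pts)
    if (stereo) {
      pl <- project_points(Xw, cam$left, cam$mount_left)
      pr <- project_points(Xw, cam$right, cam$mount_right)
      if (noise_sd > 0) {
        pl <- pl + matrix(rnorm(length(pl), 0, noise_sd), ncol = 2)
        pr <- pr + matrix(rnorm(length(pr), 0, noise_sd), ncol = 2)
      }
      list(left = pl, right = pr, pose = pose)
    } else {
      view <- camera_look_at(c(0, 0, attr(cam, "distance") %||% 3000))
      pc <- project_points(Xw, cam, view)
      if (noise_sd > 0)
        pc <- pc + matrix(rnorm(length(pc), 0, noise_sd), ncol = 2)
      list(corners = pc, pose = pose)
    }
  })
}

# ---------------------------------------------------------------------------
# block Levenberg-Marquardt for calibration problems:
# shared parameters s plus one local 6-vector per view.

lm_block <- function(resid_fun, s0, locals0, max_iter = 50, tol = 1e-12) {
  s <- s0
  locals <- locals0
  V <- length(locals)
  ns <- length(s)
  lambda <- 1e-3
  cost <- function(s, locals)
    tryCatch(sum(vapply(seq_len(V),
                        function(v) sum(resid_fun(s, locals[[v]], v)^2), 0)),
             error = function(e) Inf)
  cur <- cost(s, locals)
  for (iter in seq_len(max_iter)) {
    # assemble normal equations from per-view numeric jacobians
    n_all <- ns + 6 * V
    JTJ <- matrix(0, n_all, n_all)
    JTr <- numeric(n_all)
    eps <- 1e-7
    for (v in seq_len(V)) {
      r <- resid_fun(s, locals[[v]], v)
      Js <- matrix(0, length(r), ns)
      for (k in seq_len(ns)) {
        s2 <- s; s2[k] <- s2[k] + eps * max(1, abs(s[k]))
        Js[, k] <- (resid_fun(s2, locals[[v]], v) - r) /
          (eps * max(1, abs(s[k])))
      }
      Jl <- matrix(0, length(r), 6)
      for (k in 1:6) {
        l2 <- locals[[v]]; l2[k] <- l2[k] + eps
        Jl[, k] <- (resid_fun(s, l2, v) - r) / eps
      }
      is <- seq_len(ns)
      il <- ns + 6 * (v - 1) + 1:6
      JTJ[is, is] <- JTJ[is, is] + crossprod(Js)
      JTJ[il, il] <- crossprod(Jl)
      JTJ[is, il] <- crossprod(Js, Jl)
      JTJ[il, is] <- t(JTJ[is, il])
      JTr[is] <- JTr[is] + crossprod(Js, r)
      JTr[il] <- crossprod(Jl, r)
    }
    improved <- FALSE
    for (try in 1:8) {
      A <- JTJ + lambda * diag(diag(JTJ) + 1e-12, n_all)
      delta <- tryCatch(solve(A, -JTr), error = function(e) NULL)
      if (!is.null(delta)) {
        s_new <- s + delta[seq_len(ns)]
        locals_new <- lapply(seq_len(V), function(v)
          locals[[v]] + delta[ns + 6 * (v - 1) + 1:6])
        new <- cost(s_new, locals_new)
        if (is.finite(new) && new < cur) {
          s <- s_new; locals <- locals_new
          improved <- TRUE
          conv <- (cur - new) < tol * max(cur, 1e-300)
          cur <- new
          lambda <- max(lambda / 4, 1e-12)
          if (conv) return(list(s = s, locals = locals, cost = cur))
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  list(s = s, locals = locals, cost = cur)
}

# pack/unpack a view pose as c(w (rodrigues), t)
pose_to_wt <- function(tf) {
  R <- tf$R
  # rotation log map, stable near 0 and pi
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) {
    w <- c(0, 0, 0)
  } else if (ang < pi - 1e-4) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    w <- ang * ax / (2 * sin(ang))
  } else {
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    k <- which.max(ax)
    sgn <- c(1, 1, 1)
    for (j in setdiff(1:3, k)) sgn[j] <- ifelse(B[k, j] < 0, -1, 1)
    ax <- ax * sgn * ifelse(k == 1, 1, 1)
    ax <- ax / sqrt(sum(ax^2))
    # fix overall sign using the skew part where it is non-zero
    sk <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(ax * sk) < 0) ax <- -ax
    w <- ang * ax
  }
  c(w, tf$t)
}

wt_to_pose <- function(wt) rigid_transform(rodrigues(wt[1:3]), wt[4:6])

#' Estimate camera intrinsics from planar calibration views
#'
#' Planar calibration from detected corner sets of a board of known
#' geometry. Focal lengths are initialised from the orthonormality
#' constraints that each board homography places on the image of the
#' absolute conic (principal point fixed at the image centre for the
#' initial step, a stabilising choice for very narrow fields of view),
#' per-view poses from homography decomposition, and all parameters --
#' fx, fy, cx, cy, radial distortion k1, k2, and the 6-DOF board pose of
#' every view -- are then refined jointly by block Levenberg-Marquardt on
#' the pixel reprojection error.
#'
#' @param observations list of views, each with a \code{corners} matrix
#'   (n x 2 px) in board row-major order (e.g. from
#'   [simulate_calibration_views()]).
#' @param board a [calibration_board_spec()].
#' @param resolution image size \code{c(width, height)} px.
#' @param estimate_distortion estimate k1, k2 (default) or hold at zero.
#' @return list with \code{intrinsics}, \code{view_poses},
#'   \code{reproj_rms} (mean, px) and \code{per_view_rms}.
#' @export
estimate_intrinsics <- function(observations, board,
                                resolution = c(720, 480),
                                estimate_distortion = TRUE) {
  V <- length(observations)
  if (V < 10) stop("estimate_intrinsics: need at least 10 views")
  pts <- calibration_board_corners(board)
  c0 <- resolution / 2
  # homographies board mm -> centred pixel coords
  Hs <- lapply(observations, function(v) {
    p <- sweep(v$corners, 2, c0)
    estimate_homography(pts[, 1:2], p)
  })
  # focal init: per-view IAC constraints, linear in (1/fx^2, 1/fy^2)
  A <- NULL; bvec <- NULL
  for (H in Hs) {
    h1 <- H[, 1]; h2 <- H[, 2]
    A <- rbind(A,
               c(h1[1] * h2[1], h1[2] * h2[2]),
               c(h1[1]^2 - h2[1]^2, h1[2]^2 - h2[2]^2))
    bvec <- c(bvec, -h1[3] * h2[3], -(h1[3]^2 - h2[3]^2))
  }
  sv <- svd(A)
  if (sv$d[2] / sv$d[1] < 1e-12)
    stop("estimate_intrinsics: degenerate view set (no orientation diversity)")
  sol <- qr.solve(A, bvec)
  if (any(sol <= 0))
    stop("estimate_intrinsics: degenerate view set (focal length unresolved)")
  fx <- 1 / sqrt(sol[1]); fy <- 1 / sqrt(sol[2])
  Kinv <- diag(c(1 / fx, 1 / fy, 1))
  locals <- lapply(Hs, function(H) {
    p <- homography_to_pose(Kinv %*% H)
    pose_to_wt(rigid_transform(p$R, p$t))
  })
  s0 <- c(fx, fy, c0[1], c0[2], 0, 0)
  obj3 <- pts
  resid_fun <- function(s, l, v) {
    X <- apply_transform(wt_to_pose(l), obj3)
    xy <- cbind(X[, 1] / X[, 3], X[, 2] / X[, 3])
    xyd <- distort_normalized(xy, c(s[5], s[6], 0, 0, 0))
    proj <- cbind(s[1] * xyd[, 1] + s[3], s[2] * xyd[, 2] + s[4])
    as.numeric(proj - observations[[v]]$corners)
  }
  if (!estimate_distortion) {
    rf <- resid_fun
    resid_fun_used <- function(s, l, v) rf(c(s, 0, 0), l, v)
    s0 <- s0[1:4]
  } else resid_fun_used <- resid_fun
  fit <- lm_block(resid_fun_used, s0, locals)
  s <- if (estimate_distortion) fit$s else c(fit$s, 0, 0)
  cam <- camera_intrinsics(s[1], s[2], s[3], s[4],
                           distortion = c(s[5], s[6], 0, 0, 0),
                           resolution = resolution)
  per_view <- vapply(seq_len(V), function(v) {
    r <- resid_fun(s, fit$locals[[v]], v)
    sqrt(mean(r^2))                      # per-coordinate RMS (px)
  }, 0)
  list(intrinsics = cam,
       view_poses = lapply(fit$locals, wt_to_pose),
       reproj_rms = mean(per_view),
       per_view_rms = per_view)
}

# project to SO(3): mean rotation of a list of rotation matrices
mean_rotation <- function(Rs) {
  M <- Reduce(`+`, Rs)
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' Estimate stereo extrinsic parameters
#'
#' Computes the rigid transform mapping right-camera coordinates to the
#' left-camera frame from paired synchronous views of the calibration
#' board, given both cameras' intrinsics. Per-view board poses are
#' solved by planar PnP in each camera; the per-view relative transforms
#' are averaged (rotations projected to SO(3)), and the extrinsic plus
#' all left-camera board poses are refined jointly on the two-view pixel
#' reprojection error.
#'
#' @param observations list of paired views with \code{left} and
#'   \code{right} corner matrices.
#' @param board a [calibration_board_spec()].
#' @param left,right [camera_intrinsics()].
#' @return list with \code{extrinsic} ([rigid_transform()], right ->
#'   left), \code{reproj_rms} (px) and \code{baseline} (mm).
#' @export
estimate_stereo_extrinsics <- function(observations, board, left, right) {
  V <- length(observations)
  if (V < 3) stop("estimate_stereo_extrinsics: need at least 3 paired views")
  bad <- vapply(observations, function(v)
    is.null(v$left) || is.null(v$right) || nrow(v$left) != nrow(v$right),
    TRUE)
  if (any(bad))
    stop("estimate_stereo_extrinsics: unpaired or mismatched views")
  pts <- calibration_board_corners(board)
  rel <- lapply(observations, function(v) {
    Tl <- solve_planar_pnp(v$left, pts, left)$transform
    Tr <- solve_planar_pnp(v$right, pts, right)$transform
    # board->left = Tl, board->right = Tr; right->left = Tl o Tr^-1
    compose_transform(Tl, invert_transform(Tr))
  })
  E0 <- rigid_transform(mean_rotation(lapply(rel, `[[`, "R")),
                        rowMeans(vapply(rel, `[[`, numeric(3), "t")))
  locals <- lapply(observations, function(v)
    pose_to_wt(solve_planar_pnp(v$left, pts, left)$transform))
  resid_fun <- function(s, l, v) {
    E <- wt_to_pose(s)
    Tl <- wt_to_pose(l)
    Tr <- compose_transform(invert_transform(E), Tl)
    pl <- project_points(pts, left, Tl)
    pr <- project_points(pts, right, Tr)
    c(as.numeric(pl - observations[[v]]$left),
      as.numeric(pr - observations[[v]]$right))
  }
  fit <- lm_block(resid_fun, pose_to_wt(E0), locals)
  E <- wt_to_pose(fit$s)
  n_res <- sum(vapply(observations, function(v) 4 * nrow(v$left), 0))
  list(extrinsic = E,
       reproj_rms = sqrt(fit$cost / n_res),
       baseline = sqrt(sum(E$t^2)))
}
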