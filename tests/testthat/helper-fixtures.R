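# Shared fixtures: rendered frames are expensive, so they are built
# lazily once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fix_spec <- function() fixture("spec", function() marker_spec())
fix_cam <- function() fixture("cam", function() camera_preset("external"))
fix_rig <- function() fixture("rig", function() stereo_rig_preset())
fix_view <- function() fixture("view", function() camera_look_at(c(0, 0, 3000)))

# noiseless marker render at a pose, cached by label
fix_marker_frame <- function(label, pose, opts = render_options(),
                             camera = fix_cam(), viewing = fix_view()) {
  fixture(paste0("frame_", label), function()
    render_marker_view(pose, camera, fix_spec(), opts, viewing = viewing))
}

fix_analysis <- function(label, pose, corners = FALSE) {
  fixture(paste0("analysis_", label), function()
    analyze_marker_frame(fix_marker_frame(label, pose), fix_spec(),
                         corners = corners))
}

# independent two-ray intersection oracle: closest point between the
# back-projected rays (midpoint of the common perpendicular)
ray_intersect_oracle <- function(left_pts, right_pts, rig) {
  E <- rig$extrinsic
  C2 <- E$t                              # right camera centre in left frame
  xl <- undistort_points(left_pts, rig$left)
  xr <- undistort_points(right_pts, rig$right)
  out <- matrix(0, nrow(xl), 3)
  for (i in seq_len(nrow(xl))) {
    d1 <- c(xl[i, ], 1)
    d2 <- drop(E$R %*% c(xr[i, ], 1))
    # p = s*d1 ; q = C2 + t*d2 ; minimise |p-q|
    A <- cbind(d1, -d2)
    st <- solve(crossprod(A), crossprod(A, C2))
    p <- st[1] * d1
    q <- C2 + st[2] * d2
    out[i, ] <- (p + q) / 2
  }
  out
}

# brute-force rigid registration oracle: direct 6-parameter least
# squares on the sum of squared pair distances
rigid_lsq_oracle <- function(src, tgt) {
  obj <- function(p) {
    R <- euler_to_matrix(p[4], p[5], p[6])
    sum((sweep(src %*% t(R), 2, -p[1:3]) - tgt)^2)
  }
  fit <- stats::optim(rep(0, 6), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit
}

K_mat <- function(cam) {
  matrix(c(cam$fx, 0, cam$cx, 0, cam$fy, cam$cy, 0, 0, 1), 3, byrow = TRUE)
}

# dominant periodogram frequency (cycles per sample)
dominant_freq <- function(x) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]
  which.max(sp) / n
}
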