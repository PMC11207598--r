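# Synthetic renderer for marker views: replaces the physical rig so that
# every stage of the analysis pipeline can be exercised against known
# ground truth.

#' Rendering options
#'
#' @param noise_sd per-pixel Gaussian noise (grey levels).
#' @param blur_sd Gaussian optical/defocus blur (px) applied after
#'   downsampling; approximates the camera point-spread function.
#' @param illumination in-plane illumination gradient
#'   \code{c(gx, gy)} as fractional change across the half-image.
#' @param glare list of glare patches \code{c(cx, cy, rx, ry, intensity)}
#'   (px, grey levels), added as elliptical Gaussians.
#' @param occlusion list of pixel rectangles \code{c(xmin, xmax, ymin,
#'   ymax)} painted over with the background level.
#' @param background background grey level.
#' @param white_level,black_level reflectance extremes of the printed
#'   face (grey levels).
#' @param supersample supersampling factor for anti-aliasing; the fine
#'   gratings approach the pixel pitch, so rendering samples 4x4 rays per
#'   pixel by default and box-averages.
#' @param seed seed for the pixel noise (NULL = use current RNG state).
#' @return object of class \code{render_options}.
#' @export
render_options <- function(noise_sd = 0, blur_sd = 0.7,
                           illumination = c(0, 0), glare = list(),
                           occlusion = list(), background = 90,
                           white_level = 215, black_level = 25,
                           supersample = 4, seed = NULL) {
  stopifnot(noise_sd >= 0, blur_sd >= 0, supersample >= 1)
  structure(list(noise_sd = noise_sd, blur_sd = blur_sd,
                 illumination = illumination, glare = glare,
                 occlusion = occlusion, background = background,
                 white_level = white_level, black_level = black_level,
                 supersample = as.integer(supersample), seed = seed),
            class = "render_options")
}

# square-wave print transmittance: black ink lines at 50% duty cycle.
# `u` is the coordinate along the grating axis (mm), `f` lines/mm, and
# `w` the footprint (mm) of one rendered sample, over which the binary
# wave is box-averaged analytically -- i.e. exact area sampling, so the
# carrier does not alias against the sampling grid.
square_transmittance <- function(u, f, w = 0, t_min = 0.08) {
  if (w <= 0) return(t_min + (1 - t_min) * (sin(2 * pi * f * u) > 0))
  Fint <- function(x) 0.5 * floor(x) + pmin(x - floor(x), 0.5)
  frac_on <- (Fint(f * u + f * w / 2) - Fint(f * u - f * w / 2)) / (f * w)
  t_min + (1 - t_min) * frac_on
}

# fraction of a width-w box (centred at signed distance d from an edge)
# lying on the positive side of the edge; w = 0 degrades to a hard test
box_coverage <- function(d, w) {
  if (w <= 0) return(as.numeric(d >= 0))
  pmin(pmax(d / w + 0.5, 0), 1)
}

# box mean of the +/-1 period-2 square wave (+1 on [0,1)) at position u
square_pm_mean <- function(u, w) {
  if (w <= 0) return(ifelse(floor(u) %% 2 == 0, 1, -1))
  G <- function(x) {
    m <- x %% 2
    ifelse(m <= 1, m, 2 - m)             # periodic integral of the wave
  }
  (G(u + w / 2) - G(u - w / 2)) / w
}

# evaluate the marker face (reflectance in grey levels) at marker-frame
# coordinates; dirs are unit ray directions in the marker frame (camera
# to surface) used for the refracted moire sampling.  `footprint` is the
# (wx, wy) extent in mm of one rendered sample; all pattern edges are
# area-averaged over it analytically so that sub-sample pose changes
# move the rendered edges continuously (no spatial quantisation).
marker_face_value <- function(spec, X, Y, dirs, opts, footprint = c(0, 0)) {
  hw <- spec$face_size[1] / 2; hh <- spec$face_size[2] / 2
  wx <- footprint[1]; wy <- footprint[2]
  wl <- opts$white_level; bl <- opts$black_level
  cov_face <- box_coverage(hw - abs(X), wx) * box_coverage(hh - abs(Y), wy)
  val <- opts$background + cov_face * (wl - opts$background)
  # checkerboard: product of two +/-1 square waves, box-averaged exactly
  ext <- checkerboard_extent(spec)
  sq <- spec$checkerboard$square
  near <- X >= ext[1] - sq & X <= ext[2] + sq & Y >= ext[3] - sq &
          Y <= ext[4] + sq
  if (any(near)) {
    u <- (X[near] - ext[1]) / sq
    v2 <- (Y[near] - ext[3]) / sq
    m2 <- square_pm_mean(u, wx / sq) * square_pm_mean(v2, wy / sq)
    checker <- (wl + bl) / 2 - m2 * (wl - bl) / 2
    cov <- box_coverage(X[near] - ext[1], wx) *
           box_coverage(ext[2] - X[near], wx) *
           box_coverage(Y[near] - ext[3], wy) *
           box_coverage(ext[4] - Y[near], wy)
    val[near] <- val[near] + cov * (checker - val[near])
  }
  # anchor squares: 6x6 cell pattern, separable box-blended at cell edges
  for (a in spec$aruco_anchors) {
    s <- a$size / 2
    cell <- a$size / 6
    sel <- X >= a$center[1] - s - cell & X <= a$center[1] + s + cell &
           Y >= a$center[2] - s - cell & Y <= a$center[2] + s + cell
    if (!any(sel)) next
    pat <- aruco_pattern(a$id)                 # rows top->bottom
    tx <- (X[sel] - (a$center[1] - s)) / cell  # 0..6 across the square
    ty <- ((a$center[2] + s) - Y[sel]) / cell
    wcx <- wx / cell; wcy <- wy / cell
    # separable blend across the nearest cell edge (footprint << cell):
    # at position t the box straddles edge e = round(t), mixing cells
    # e-1 and e with the coverage fraction
    r_e <- round(ty)
    r_lo <- pmin(pmax(r_e - 1, 0), 5); r_hi <- pmin(pmax(r_e, 0), 5)
    a_r <- box_coverage(ty - r_e, wcy)
    c_e <- round(tx)
    c_lo <- pmin(pmax(c_e - 1, 0), 5); c_hi <- pmin(pmax(c_e, 0), 5)
    a_c <- box_coverage(tx - c_e, wcx)
    sample_row <- function(ri) {
      pat[cbind(ri + 1, c_lo + 1)] * (1 - a_c) +
        pat[cbind(ri + 1, c_hi + 1)] * a_c
    }
    pv <- sample_row(r_lo) * (1 - a_r) + sample_row(r_hi) * a_r
    anchor_val <- bl + pv * (wl - bl)
    cov <- box_coverage(tx, wcx) * box_coverage(6 - tx, wcx) *
           box_coverage(ty, wcy) * box_coverage(6 - ty, wcy)
    val[sel] <- val[sel] + cov * (anchor_val - val[sel])
  }
  # moire gratings: product of the two printed square waves, the rear
  # (f_front) layer sampled where the refracted ray crosses it.  The
  # transverse displacement over thickness d of a unit ray with
  # transverse component (dx, dy) is d * (dx, dy) / sqrt(n^2 - st^2)
  # (Snell), st^2 = dx^2 + dy^2.
  for (g in spec$gratings) {
    r <- g$region
    sel <- X >= r[1] & X <= r[2] & Y >= r[3] & Y <= r[4]
    if (!any(sel)) next
    dx <- dirs[sel, 1]; dy <- dirs[sel, 2]
    st2 <- dx^2 + dy^2
    denom <- sqrt(g$n_refractive^2 - st2)
    if (g$axis == "yaw") {
      cc <- X[sel]
      delta <- g$d * dx / denom
      w <- footprint[1]
    } else {
      cc <- Y[sel]
      delta <- g$d * dy / denom
      w <- footprint[2]
    }
    t_near <- square_transmittance(cc, g$f_back, w)
    t_far <- square_transmittance(cc + delta, g$f_front, w)
    val[sel] <- opts$white_level * t_near * t_far
  }
  val
}

#' Render a marker view
#'
#' Renders a grayscale camera frame of the fiducial marker at a
#' commanded 6-DOF pose. The planar face (checkerboard, anchors) is
#' rendered by exact perspective projection; the moire regions are
#' rendered from first principles by sampling both grating layers along
#' the refracted viewing ray through the substrate, so the beat-pattern
#' phase responds to through-plane rotation as an emergent property
#' rather than by construction.
#'
#' @param pose commanded [pose6dof()] of the marker (relative to the
#'   reference marker frame = world frame).
#' @param camera a [camera_intrinsics()].
#' @param spec a [marker_spec()].
#' @param opts a [render_options()].
#' @param viewing world-to-camera [rigid_transform()]; defaults to a
#'   camera on the optical axis at 3 m.
#' @param timestamp,camera_id frame metadata.
#' @return a [new_frame()].
#' @export
render_marker_view <- function(pose, camera, spec, opts = render_options(),
                               viewing = NULL, timestamp = 0,
                               camera_id = "cam") {
  if (is.null(viewing)) viewing <- camera_look_at(c(0, 0, 3000))
  T_mc <- compose_transform(viewing, pose_to_transform(pose))
  # marker centre must project inside the image
  ctr <- project_camera_points(matrix(apply_transform(T_mc, c(0, 0, 0)),
                                      1, 3), camera)
  W <- camera$resolution[1]; H <- camera$resolution[2]
  if (ctr[1] < 1 || ctr[1] > W || ctr[2] < 1 || ctr[2] > H ||
      apply_transform(T_mc, c(0, 0, 0))[3] <= 0)
    stop("render_marker_view: marker outside the camera field of view")
  S <- opts$supersample
  inv <- invert_transform(T_mc)
  O <- inv$t                              # camera centre, marker frame
  Rcm <- inv$R
  # marker-mm footprint of one supersample (for analytic grating AA)
  zc <- apply_transform(T_mc, c(0, 0, 0))[3]
  footprint <- c(zc / camera$fx, zc / camera$fy) / S
  img <- matrix(0, H, W)
  rows_per_chunk <- max(1L, floor(4e6 / (W * S * S)))
  us <- ((seq_len(W * S) - 0.5) / S - camera$cx) / camera$fx
  for (r0 in seq(1, H, by = rows_per_chunk)) {
    r1 <- min(H, r0 + rows_per_chunk - 1)
    nr <- (r1 - r0 + 1)
    vs <- ((seq((r0 - 1) * S + 1, r1 * S) - 0.5) / S - camera$cy) / camera$fy
    xn <- matrix(us, nrow = nr * S, ncol = W * S, byrow = TRUE)
    yn <- matrix(vs, nrow = nr * S, ncol = W * S)
    if (any(camera$distortion != 0)) {
      und <- undistort_normalized(cbind(as.numeric(xn), as.numeric(yn)),
                                  camera$distortion)
      xn <- matrix(und[, 1], nrow = nr * S); yn <- matrix(und[, 2], nrow = nr * S)
    }
    # ray directions in the marker frame
    d1 <- Rcm[1, 1] * xn + Rcm[1, 2] * yn + Rcm[1, 3]
    d2 <- Rcm[2, 1] * xn + Rcm[2, 2] * yn + Rcm[2, 3]
    d3 <- Rcm[3, 1] * xn + Rcm[3, 2] * yn + Rcm[3, 3]
    nrm <- sqrt(d1^2 + d2^2 + d3^2)
    d1 <- d1 / nrm; d2 <- d2 / nrm; d3 <- d3 / nrm
    s <- -O[3] / d3
    X <- O[1] + s * d1
    Y <- O[2] + s * d2
    val <- marker_face_value(spec, as.numeric(X), as.numeric(Y),
                             cbind(as.numeric(d1), as.numeric(d2)), opts,
                             footprint = footprint)
    vm <- matrix(val, nrow = nr * S)
    # box-average S x S
    if (S > 1) {
      dim(vm) <- c(S, nr, S, W)
      m1 <- colMeans(vm)                  # (nr, S, W)
      vm <- colMeans(aperm(m1, c(2, 1, 3)))
    }
    img[r0:r1, ] <- vm
  }
  img <- post_process_frame(img, camera, opts)
  new_frame(img, timestamp = timestamp, camera_id = camera_id)
}

# blur / illumination / glare / occlusion / noise / clipping
post_process_frame <- function(img, camera, opts) {
  H <- nrow(img); W <- ncol(img)
  if (opts$blur_sd > 0) img <- gaussian_blur(img, opts$blur_sd)
  if (any(opts$illumination != 0)) {
    u <- (seq_len(W) - camera$cx) / (W / 2)
    v <- (seq_len(H) - camera$cy) / (H / 2)
    img <- img * outer(1 + opts$illumination[2] * v,
                       1 + opts$illumination[1] * u)
  }
  for (gl in opts$glare) {
    u <- seq_len(W); v <- seq_len(H)
    img <- img + gl[5] * outer(exp(-(v - gl[2])^2 / (2 * gl[4]^2)),
                               exp(-(u - gl[1])^2 / (2 * gl[3]^2)))
  }
  for (oc in opts$occlusion) {
    cs <- max(1, floor(oc[1])):min(W, ceiling(oc[2]))
    rs <- max(1, floor(oc[3])):min(H, ceiling(oc[4]))
    img[rs, cs] <- opts$background
  }
  if (opts$noise_sd > 0) {
    if (!is.null(opts$seed)) set.seed(opts$seed)
    img <- img + matrix(rnorm(length(img), 0, opts$noise_sd), H, W)
  }
  round(pmin(pmax(img, 0), 255))
}

# separable Gaussian blur via banded convolution matrices
gaussian_blur <- function(img, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-(-r:r)^2 / (2 * sd^2)); k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  band <- function(n) {
    M <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- pmin(n, pmax(1, i + o))        # replicate edges
      M[cbind(i, j)] <- M[cbind(i, j)] + k[o + r + 1]
    }
    M
  }
  band(H) %*% img %*% t(band(W))
}

#' Add pixel noise to a rendered frame
#'
#' Draws a fresh white-Gaussian-noise realisation on top of a (typically
#' noiseless) rendered frame; the deterministic scene content is
#' unchanged, which makes repeated noisy observations of a static scene
#' cheap.
#'
#' @param frame a [new_frame()].
#' @param noise_sd noise standard deviation (grey levels).
#' @return a noisy \code{frame}.
#' @export
add_frame_noise <- function(frame, noise_sd) {
  px <- frame$pixels + matrix(rnorm(length(frame$pixels), 0, noise_sd),
                              nrow(frame$pixels))
  px <- round(pmin(pmax(px, 0), 255))
  new_frame(px, timestamp = frame$timestamp, camera_id = frame$camera_id)
}

#' Render a stereo pair of marker views
#'
#' Renders the marker through both cameras of a rig with consistent
#' epipolar geometry (the rig's world mounts define the two viewpoints).
#'
#' @param pose commanded [pose6dof()].
#' @param rig a [stereo_rig()] with mounts (see [stereo_rig_preset()]).
#' @param spec a [marker_spec()].
#' @param opts a [render_options()].
#' @param timestamp frame metadata.
#' @return list with \code{left} and \code{right} [new_frame()]s.
#' @export
render_stereo <- function(pose, rig, spec, opts = render_options(),
                          timestamp = 0) {
  if (is.null(rig$mount_left) || is.null(rig$mount_right))
    stop("render_stereo: rig has no world mounts")
  list(left = render_marker_view(pose, rig$left, spec, opts,
                                 viewing = rig$mount_left,
                                 timestamp = timestamp, camera_id = "left"),
       right = render_marker_view(pose, rig$right, spec, opts,
                                  viewing = rig$mount_right,
                                  timestamp = timestamp, camera_id = "right"))
}
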