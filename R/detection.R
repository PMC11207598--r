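# Frame analysis: anchor detection, homography rectification, moire
# profile extraction, sinusoid phase fitting, and fine/coarse fusion
# into through-plane rotation estimates.

#' Detect anchor squares in a frame
#'
#' Finds the marker's four corner anchor squares: the frame is
#' thresholded, black connected components are extracted, candidate
#' quadrilaterals are fitted (convex hull, dominant corners, sub-pixel
#' edge refinement by fitting lines to interpolated edge crossings) and
#' decoded against the marker's 4x4 identification codes over all four
#' rotations. Only detections whose ids belong to the marker
#' specification are returned, with corners in canonical order
#' (pattern top-left first, then clockwise as seen on the face).
#'
#' If fewer than four anchors are found the frame is flagged occluded
#' and must be skipped by the caller -- the moire regions cannot be
#' localised reliably.
#'
#' @param frame a [new_frame()].
#' @param spec a [marker_spec()].
#' @param threshold black/white threshold (grey levels); estimated from
#'   the frame histogram when NULL.
#' @param min_area smallest candidate component (px); raising it towards
#'   the expected anchor size skips non-anchor blobs cheaply when the
#'   imaging scale is known.
#' @return object of class \code{aruco_detections}: list with
#'   \code{detections} (each: id, corners 4x2 px) and \code{occluded}.
#' @export
detect_aruco <- function(frame, spec, threshold = NULL, min_area = 150) {
  img <- frame$pixels
  if (is.null(threshold)) {
    q <- stats::quantile(img, c(0.01, 0.99), names = FALSE)
    threshold <- mean(q)
    if (diff(q) < 30)      # near-uniform frame: nothing to detect
      return(structure(list(detections = list(), occluded = TRUE),
                       class = "aruco_detections"))
  }
  lab <- .label_components(img < threshold)
  npx <- length(img)
  idx <- which(lab > 0)
  if (!length(idx))
    return(structure(list(detections = list(), occluded = TRUE),
                     class = "aruco_detections"))
  comp <- split(idx, lab[idx])
  H <- nrow(img)
  ids <- vapply(spec$aruco_anchors, function(a) a$id, 0)
  pats <- lapply(ids, aruco_pattern)
  found <- list()
  for (px in comp) {
    n <- length(px)
    if (n < min_area || n > 0.05 * npx) next
    # continuous image coordinates: pixel (r, c) centre is (c-0.5, r-0.5)
    rows <- ((px - 1) %% H) + 0.5
    cols <- ((px - 1) %/% H) + 0.5
    bw <- diff(range(cols)) + 1; bh <- diff(range(rows)) + 1
    if (bw / bh > 2 || bh / bw > 2) next
    if (n / (bw * bh) < 0.35 || n / (bw * bh) > 0.95) next
    quad <- extract_quad(cols, rows)
    if (is.null(quad)) next
    quad <- refine_quad_subpixel(img, quad, threshold)
    if (is.null(quad)) next
    dec <- decode_anchor(img, quad, pats, threshold)
    if (is.null(dec)) next
    found[[length(found) + 1]] <- list(id = ids[dec$which],
                                       corners = dec$corners)
  }
  # keep one detection per id (largest if duplicated)
  if (length(found)) {
    fid <- vapply(found, `[[`, 0, "id")
    found <- found[!duplicated(fid)]
  }
  structure(list(detections = found, occluded = length(found) < 4),
            class = "aruco_detections")
}

# dominant 4 corners of a blob from its convex hull:
# farthest pair -> diagonal; farthest point from the chord on each side.
extract_quad <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(hx)
  if (m < 4) return(NULL)
  D <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  i <- min(ij); j <- max(ij)
  # signed distance to the diagonal
  dx <- hx[j] - hx[i]; dy <- hy[j] - hy[i]
  dist <- (hx - hx[i]) * dy - (hy - hy[i]) * dx
  if (max(dist) <= 0 || min(dist) >= 0) return(NULL)
  k1 <- which.max(dist); k2 <- which.min(dist)
  qx <- hx[c(i, k1, j, k2)]; qy <- hy[c(i, k1, j, k2)]
  # order clockwise (image coords, y down) around the centroid
  cx <- mean(qx); cy <- mean(qy)
  o <- order(atan2(qy - cy, qx - cx))
  cbind(qx[o], qy[o])
}

# refine a quad to sub-pixel accuracy: for each edge, locate the
# threshold crossing along the outward normal at several points and fit
# a total-least-squares line; corners = intersections of adjacent lines.
refine_quad_subpixel <- function(img, quad, threshold, n_samp = 12) {
  lines <- vector("list", 4)
  cx <- mean(quad[, 1]); cy <- mean(quad[, 2])
  for (e in 1:4) {
    a <- quad[e, ]; b <- quad[e %% 4 + 1, ]
    tvals <- seq(0.2, 0.8, length.out = n_samp)
    px <- a[1] + tvals * (b[1] - a[1])
    py <- a[2] + tvals * (b[2] - a[2])
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    len <- sqrt(ex^2 + ey^2)
    nx <- ey / len; ny <- -ex / len
    # ensure normal points away from the blob centre
    if ((mean(px) - cx) * nx + (mean(py) - cy) * ny < 0) { nx <- -nx; ny <- -ny }
    ss <- seq(-2.5, 2.5, by = 0.5)
    xs <- outer(px, ss * nx, "+")
    ys <- outer(py, ss * ny, "+")
    vals <- matrix(.bilinear_sample(img, as.numeric(ys) + 0.5,
                                    as.numeric(xs) + 0.5, fill = NA_real_),
                   nrow = n_samp)
    ptx <- pty <- rep(NA_real_, n_samp)
    for (k in seq_len(n_samp)) {
      v <- vals[k, ]
      if (anyNA(v)) next
      lvl <- (min(v) + max(v)) / 2       # per-profile mid level: unbiased
      below <- v < lvl
      # inside (black) to outside (white): first crossing
      cross <- which(below[-length(v)] & !below[-1])
      if (!length(cross)) next
      c1 <- cross[length(cross)]
      f <- (lvl - v[c1]) / (v[c1 + 1] - v[c1])
      s_at <- ss[c1] + f * (ss[c1 + 1] - ss[c1])
      ptx[k] <- px[k] + s_at * nx
      pty[k] <- py[k] + s_at * ny
    }
    ok <- !is.na(ptx)
    if (sum(ok) < 4) return(NULL)
    P <- cbind(ptx[ok], pty[ok])
    mu <- colMeans(P)
    sv <- svd(sweep(P, 2, mu))
    dirv <- sv$v[, 1]
    lines[[e]] <- list(p = mu, d = dirv)
  }
  corners <- matrix(0, 4, 2)
  for (e in 1:4) {
    l1 <- lines[[if (e == 1) 4 else e - 1]]; l2 <- lines[[e]]
    A <- cbind(l1$d, -l2$d)
    if (abs(det(A)) < 1e-9) return(NULL)
    tt <- solve(A, l2$p - l1$p)
    corners[e, ] <- l1$p + tt[1] * l1$d
  }
  corners
}

# decode the 4x4 code inside a refined quad; returns the matched spec
# pattern index and the corners reordered so the pattern's top-left
# corner comes first (clockwise on the face)
decode_anchor <- function(img, quad, pats, threshold) {
  # unit cell-grid corners (x right, y down in grid space), 6x6 cells
  gridc <- rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6))
  Hm <- tryCatch(estimate_homography(gridc, quad), error = function(e) NULL)
  if (is.null(Hm)) return(NULL)
  cc <- expand.grid(gx = seq_len(6) - 0.5, gy = seq_len(6) - 0.5)
  pimg <- apply_homography(Hm, as.matrix(cc))
  v <- .bilinear_sample(img, pimg[, 2] + 0.5, pimg[, 1] + 0.5,
                        fill = NA_real_)
  if (anyNA(v)) return(NULL)
  cells <- matrix(v >= threshold, 6, 6)   # cells[gx, gy] white?
  border <- c(cells[1, ], cells[6, ], cells[, 1], cells[, 6])
  if (mean(border) > 0.15) return(NULL)   # border ring must be black
  inner <- cells[2:5, 2:5]                # inner[gx, gy]
  # bits matrix in (row = from top, col = from left) orientation:
  # grid y runs down, so row = gy, col = gx
  bits <- t(inner)
  for (p in seq_along(pats)) {
    pat <- pats[[p]][2:5, 2:5] > 0.5
    b <- bits
    for (r in 0:3) {
      if (sum(b != pat) <= 1) {
        # rotating the bits r times clockwise aligned them with the
        # pattern; the pattern's top-left corner is quad corner 1 + r
        o <- ((0:3 + r) %% 4) + 1
        return(list(which = p, corners = quad[o, , drop = FALSE],
                    rotation = r))
      }
      b <- rotate_bits(b)
    }
  }
  NULL
}

#' Rectify the marker face to a canonical grid
#'
#' Estimates the homography mapping the marker plane (mm) to the image
#' from the 16 detected anchor corners and resamples the face onto a
#' rectilinear grid of fixed scale, after which every moire region has a
#' defined pixel position.
#'
#' @param frame a [new_frame()].
#' @param detections an \code{aruco_detections} with all four anchors.
#' @param spec a [marker_spec()].
#' @param scale output sampling density (px/mm).
#' @param regions optional list of mm rectangles \code{c(xmin, xmax,
#'   ymin, ymax)} to resample instead of the full face (the grating
#'   regions, typically) -- the geometry is identical, only less area is
#'   sampled.
#' @return object of class \code{rectified_marker}: \code{pixels} (full
#'   face) or \code{region_pixels}, plus the mm-to-px homography \code{H}
#'   and the grid description.
#' @export
rectify_marker <- function(frame, detections, spec, scale = 10,
                           regions = NULL) {
  if (inherits(detections, "aruco_detections")) {
    if (detections$occluded)
      stop("rectify_marker: frame is occluded (fewer than 4 anchors)")
    dets <- detections$detections
  } else dets <- detections
  ideal <- anchor_corners(spec)
  src <- NULL; dst <- NULL
  for (d in dets) {
    ic <- ideal[[as.character(d$id)]]
    if (is.null(ic)) next
    src <- rbind(src, ic[, 1:2])
    dst <- rbind(dst, d$corners)
  }
  if (is.null(src) || nrow(src) < 16)
    stop("rectify_marker: need all four anchors of the marker spec")
  H <- estimate_homography(src, dst)     # marker mm -> image px
  hw <- spec$face_size[1] / 2; hh <- spec$face_size[2] / 2
  sample_grid <- function(r) {
    xs <- seq(r[1] + 0.5 / scale, r[2] - 1e-9, by = 1 / scale)
    ys <- seq(r[4] - 0.5 / scale, r[3] + 1e-9, by = -1 / scale)
    g <- expand.grid(x = xs, y = ys)
    p <- apply_homography(H, as.matrix(g))
    v <- .bilinear_sample(frame$pixels, p[, 2] + 0.5, p[, 1] + 0.5, fill = 0)
    matrix(v, nrow = length(ys), byrow = TRUE)
  }
  out <- list(H = H, scale = scale, spec_face = spec$face_size)
  if (is.null(regions)) {
    out$pixels <- sample_grid(c(-hw, hw, -hh, hh))
    out$origin <- c(-hw, hh)
  } else {
    out$region_pixels <- lapply(regions, sample_grid)
    out$regions <- regions
  }
  class(out) <- "rectified_marker"
  out
}

#' Extract a moire profile from the rectified marker
#'
#' Collects the grayscale pixel lines of one grating region along its
#' long edge and averages them into a single 1-D moire signal: for a
#' yaw-sensing region the columns are averaged over the rows it spans,
#' for pitch the rows over the columns, with the profile coordinate
#' always increasing along the positive marker axis.
#'
#' @param rectified a [rectify_marker()] result (full face, or with the
#'   grating's region included in \code{regions}).
#' @param grating a [moire_grating_pair()].
#' @param spec a [marker_spec()].
#' @return object of class \code{moire_profile}: \code{values} (grey),
#'   \code{positions} (px along the profile), \code{n_lines},
#'   \code{mm_per_px}, \code{grating}.
#' @export
extract_moire_profile <- function(rectified, grating, spec) {
  r <- grating$region
  if (!is.null(rectified$pixels)) {
    hw <- spec$face_size[1] / 2; hh <- spec$face_size[2] / 2
    if (r[1] < -hw || r[2] > hw || r[3] < -hh || r[4] > hh)
      stop("extract_moire_profile: region outside the rectified image")
    sc <- rectified$scale
    x0 <- rectified$origin[1]; y0 <- rectified$origin[2]
    cs <- round((r[1] - x0) * sc + 0.5):round((r[2] - x0) * sc - 0.5 + 1)
    rs <- round((y0 - r[4]) * sc + 0.5):round((y0 - r[3]) * sc - 0.5 + 1)
    cs <- cs[cs >= 1 & cs <= ncol(rectified$pixels)]
    rs <- rs[rs >= 1 & rs <= nrow(rectified$pixels)]
    block <- rectified$pixels[rs, cs, drop = FALSE]
  } else {
    hit <- which(vapply(rectified$regions, function(q) all(q == r), TRUE))
    if (!length(hit))
      stop("extract_moire_profile: grating region was not rectified")
    block <- rectified$region_pixels[[hit[1]]]
  }
  if (grating$axis == "yaw") {
    vals <- colMeans(block)
    n_lines <- nrow(block)
  } else {
    vals <- rev(rowMeans(block))         # rows run y-down; profile along +y
    n_lines <- ncol(block)
  }
  mm_per_px <- 1 / rectified$scale
  span_mm <- length(vals) * mm_per_px
  if (span_mm * beat_frequency(grating) < 2)
    stop("extract_moire_profile: profile spans fewer than 2 beat periods")
  structure(list(values = as.numeric(vals),
                 positions = seq_along(vals) - 1,
                 n_lines = n_lines, mm_per_px = mm_per_px,
                 grating = grating),
            class = "moire_profile")
}

# zero-phase moving average of fractional width w (samples): the kernel
# is a sampled continuous boxcar, so a sinusoid of period exactly w is
# nulled; used to notch the printed carrier lines out of a profile
frac_box_filter <- function(v, w) {
  hw <- ceiling(w / 2 - 0.5)
  j <- -hw:hw
  k <- pmax(0, pmin(j + 0.5, w / 2) - pmax(j - 0.5, -w / 2))
  k <- k / sum(k)
  n <- length(v)
  if (n <= 2 * hw + 2) return(list(values = v, trim = 0))
  out <- stats::filter(v, k, sides = 2)
  list(values = as.numeric(out[(hw + 1):(n - hw)]), trim = hw)
}

#' Fit a sinusoid to a moire profile
#'
#' Least-squares fit of \code{A * sin(omega * s - phi) + b} to the
#' mean-centred profile. The spatial frequency is initialised at the
#' nominal beat frequency of the grating pair and allowed to vary (a
#' variable-projection search over omega with the linear parameters
#' solved exactly, followed by a Levenberg-Marquardt polish), absorbing
#' fabrication or scale imperfections. The result is canonicalised to
#' positive amplitude with the phase wrapped to (-pi, pi].
#'
#' A profile whose fitted amplitude is below the noise floor is returned
#' with \code{low_confidence = TRUE} (e.g. a featureless region); a fit
#' whose frequency runs into the search bracket raises an error carrying
#' the residual diagnostics.
#'
#' @param profile a [extract_moire_profile()] result.
#' @param omega0 initial angular frequency (rad/px); default from the
#'   grating's nominal beat frequency.
#' @param bracket search bracket around \code{omega0} (fractional).
#' @return object of class \code{phase_measurement}: \code{amplitude},
#'   \code{omega}, \code{phase}, \code{offset}, \code{residual_rms},
#'   \code{fitted}, \code{low_confidence}.
#' @export
fit_moire_phase <- function(profile, omega0 = NULL, bracket = 0.25) {
  s <- profile$positions
  v <- profile$values
  if (!is.null(profile$grating) && !is.null(profile$mm_per_px)) {
    # notch the two printed carrier frequencies (zero-phase): the beat
    # (much longer period) passes essentially unattenuated
    g <- profile$grating
    for (f in c(g$f_front, g$f_back)) {
      fb <- frac_box_filter(v, 1 / (f * profile$mm_per_px))
      if (fb$trim > 0) {
        v <- fb$values
        s <- s[(fb$trim + 1):(length(s) - fb$trim)]
      }
    }
    if (is.null(omega0))
      omega0 <- 2 * pi * beat_frequency(profile$grating) * profile$mm_per_px
  }
  if (is.null(omega0))
    stop("fit_moire_phase: omega0 required when the profile has no grating")
  mu <- mean(v)
  v <- v - mu                            # mean-centred before fitting
  s_mid <- mean(s)
  sc <- s - s_mid                        # centre the phase reference
  # the beat of two square-wave prints carries odd harmonics; fitting
  # them jointly keeps the fundamental's phase unbiased on short windows
  harmonics <- if (!is.null(profile$grating)) c(1, 3, 5) else 1
  basis <- function(w) {
    B <- do.call(cbind, lapply(harmonics, function(h)
      cbind(sin(h * w * sc), cos(h * w * sc))))
    cbind(B, 1)
  }
  rss_for <- function(w) sum(stats::lm.fit(basis(w), v)$residuals^2)
  # the residual landscape over omega is multimodal (lobes about one
  # cycle-per-window apart): coarse grid first, then a local polish
  grid <- seq(omega0 * (1 - bracket), omega0 * (1 + bracket),
              length.out = 61)
  rss_g <- vapply(grid, rss_for, 0)
  gi <- which.min(rss_g)
  lo <- grid[max(1, gi - 1)]; hi <- grid[min(length(grid), gi + 1)]
  opt <- stats::optimize(rss_for, c(lo, hi), tol = omega0 * 1e-9)
  w <- opt$minimum
  B <- basis(w)
  cf <- stats::lm.fit(B, v)$coefficients
  A <- sqrt(cf[1]^2 + cf[2]^2)
  phi_mid <- atan2(-cf[2], cf[1])
  phi <- phi_mid + w * s_mid             # Eq.-3 phase referred to s = 0
  resid <- v - (B %*% cf)
  rms <- sqrt(mean(resid^2))
  L <- length(s)
  low_conf <- A < max(1.0, 6 * rms * sqrt(2 / L))
  if (!low_conf &&
      (w <= omega0 * (1 - bracket) * 1.001 || w >= omega0 * (1 + bracket) * 0.999))
    stop(sprintf(paste0("fit_moire_phase: frequency ran into the search ",
                        "bracket (omega=%.4g, nominal %.4g, residual rms ",
                        "%.3g)"), w, omega0, rms))
  structure(list(amplitude = unname(A), omega = unname(w),
                 phase = unname(wrap_pi(phi)),
                 phase_mid = unname(wrap_pi(phi_mid)),
                 offset = unname(mu + cf[length(cf)]),
                 residual_rms = rms,
                 fitted = as.numeric(B %*% cf) + mu,
                 low_confidence = low_conf),
            class = "phase_measurement")
}

#' @export
print.phase_measurement <- function(x, ...) {
  cat(sprintf(
    "phase measurement: A=%.3g omega=%.5g phi=%.5g rad b=%.4g rms=%.3g%s\n",
    x$amplitude, x$omega, x$phase, x$offset, x$residual_rms,
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

# Sign relating a positive through-plane rotation to the measured beat
# phase shift, per axis.  Geometry: a positive yaw tips the camera
# direction towards +X in the marker frame, displacing the rear grating
# sample towards +X, which *retards* the fitted phase phi of
# A sin(w s - phi) (the beat advances as cos(w c + 2 pi f1 delta)); a
# positive pitch tips the view towards +Y giving the opposite sense
# along the pitch profile.
moire_axis_sign <- function(axis) if (axis == "yaw") -1 else 1

#' Through-plane rotation from fine and coarse phase measurements
#'
#' Converts the phase differences between a current and a reference
#' measurement of one axis' fine and coarse grating pairs into a single
#' rotation angle. Both channels are only known modulo their own phase
#' wrap, so the integer wrap counts of the two channels are searched
#' jointly for the combination whose angles agree (dual-wavelength
#' disambiguation); the fine-channel angle of the best pair is returned
#' -- highly sensitive tracking over the combined dynamic range. If no
#' combination agrees to within \code{max_disagreement} the channels are
#' inconsistent (e.g. a corrupted fit) and an error is raised.
#'
#' @param current,reference lists with \code{fine} and \code{coarse}
#'   [fit_moire_phase()] measurements; the reference is the session's
#'   reference pose (first non-occluded frame by convention).
#' @param gratings list with \code{fine} and \code{coarse}
#'   [moire_grating_pair()]s (same axis).
#' @param max_wraps wrap counts searched for the fine channel (the
#'   coarse channel searches one wrap either side).
#' @param max_disagreement largest tolerated fine/coarse angle
#'   difference (degrees); consistent fits agree to a few hundredths.
#' @return rotation angle in degrees, with attributes \code{coarse}
#'   (matched coarse-channel angle) and \code{wraps} (fine wrap count).
#' @export
through_plane_rotation <- function(current, reference, gratings,
                                   max_wraps = 3, max_disagreement = 0.5) {
  axis <- gratings$fine$axis
  sgn <- moire_axis_sign(axis)
  # difference the phases at the profile centre (decoupled from the
  # fitted-frequency jitter) when available
  ph <- function(m) if (!is.null(m$phase_mid)) m$phase_mid else m$phase
  dphi_f <- wrap_pi(ph(current$fine) - ph(reference$fine)) * sgn
  dphi_c <- wrap_pi(ph(current$coarse) - ph(reference$coarse)) * sgn
  kf <- -max_wraps:max_wraps
  cand_f <- vapply(kf, function(k)
    rotation_from_phase(dphi_f + 2 * pi * k, gratings$fine), 0)
  kc <- -1:1
  cand_c <- vapply(kc, function(k)
    rotation_from_phase(dphi_c + 2 * pi * k, gratings$coarse), 0)
  D <- abs(outer(cand_f, cand_c, "-"))
  # best agreeing pair; ties broken towards the smaller rotation
  best <- which(D == min(D), arr.ind = TRUE)
  if (nrow(best) > 1)
    best <- best[which.min(abs(cand_f[best[, 1]])), , drop = FALSE]
  theta <- cand_f[best[1, 1]]
  theta_c <- cand_c[best[1, 2]]
  if (abs(theta - theta_c) > max_disagreement)
    stop(sprintf(paste0("through_plane_rotation: fine/coarse channels ",
                        "disagree (%.3g vs %.3g deg)"), theta, theta_c))
  structure(theta, coarse = theta_c, wraps = kf[best[1, 1]])
}

#' Detect and refine checkerboard corners of the marker
#'
#' Projects the ideal checkerboard inner corners through the anchor
#' homography as initial guesses and refines each to sub-pixel accuracy
#' with the classic gradient-orthogonality (saddle-point) iteration used
#' by calibration toolchains.
#'
#' @param frame a [new_frame()].
#' @param detections an \code{aruco_detections} (all four anchors).
#' @param spec a [marker_spec()].
#' @param win half window for refinement (px).
#' @param iters refinement iterations.
#' @return n x 2 pixel corner positions (row-major from the marker's
#'   top-left inner corner).
#' @export
detect_checker_corners <- function(frame, detections, spec, win = 5,
                                   iters = 4) {
  rect <- rectify_marker(frame, detections, spec, regions = list())
  H <- rect$H
  init <- apply_homography(H, checkerboard_corners(spec)[, 1:2])
  refine_corners_subpix(frame$pixels, init, win = win, iters = iters)
}

refine_corners_subpix <- function(img, pts, win = 5, iters = 4) {
  # central-difference gradients
  H <- nrow(img); W <- ncol(img)
  gx <- img[, c(2:W, W)] - img[, c(1, 1:(W - 1))]
  gy <- img[c(2:H, H), ] - img[c(1, 1:(H - 1)), ]
  off <- expand.grid(dx = -win:win, dy = -win:win)
  wgt <- exp(-(off$dx^2 + off$dy^2) / (2 * (win / 2)^2))
  out <- pts
  for (i in seq_len(nrow(pts))) {
    q <- pts[i, ]
    for (it in seq_len(iters)) {
      xs <- q[1] + off$dx; ys <- q[2] + off$dy
      gxv <- .bilinear_sample(gx, ys + 0.5, xs + 0.5, fill = 0)
      gyv <- .bilinear_sample(gy, ys + 0.5, xs + 0.5, fill = 0)
      a <- sum(wgt * gxv * gxv); b <- sum(wgt * gxv * gyv)
      c2 <- sum(wgt * gyv * gyv)
      bx <- sum(wgt * (gxv * gxv * xs + gxv * gyv * ys))
      by <- sum(wgt * (gxv * gyv * xs + gyv * gyv * ys))
      det2 <- a * c2 - b * b
      if (det2 < 1e-9) break
      qn <- c((c2 * bx - b * by) / det2, (a * by - b * bx) / det2)
      if (sum((qn - q)^2) < 1e-12) { q <- qn; break }
      q <- qn
    }
    out[i, ] <- q
  }
  out
}

#' Analyse one marker frame
#'
#' Runs the full monocular frame pipeline: anchor detection, homography
#' rectification of the grating regions, moire profile extraction and
#' phase fitting for all four gratings, and checkerboard corner
#' refinement. Occluded frames return immediately with
#' \code{occluded = TRUE} and contribute no measurements.
#'
#' @param frame a [new_frame()].
#' @param spec a [marker_spec()].
#' @param scale rectification density (px/mm).
#' @param corners also refine checkerboard corners.
#' @param threshold black/white threshold forwarded to [detect_aruco()].
#' @param axes which moire axes to analyse (both by default).
#' @param min_area candidate size floor forwarded to [detect_aruco()].
#' @return list: \code{occluded}, \code{detections}, \code{phases}
#'   (named list of [fit_moire_phase()] results per grating),
#'   \code{corners} (n x 2 px or NULL).
#' @export
analyze_marker_frame <- function(frame, spec, scale = 10, corners = TRUE,
                                 threshold = NULL, axes = c("pitch", "yaw"),
                                 min_area = 150) {
  det <- detect_aruco(frame, spec, threshold = threshold,
                      min_area = min_area)
  if (det$occluded)
    return(list(occluded = TRUE, detections = det, phases = NULL,
                corners = NULL))
  use <- vapply(spec$gratings, function(g) g$axis %in% axes, TRUE)
  gr <- spec$gratings[use]
  regions <- lapply(gr, function(g) g$region)
  rect <- rectify_marker(frame, det, spec, scale = scale,
                         regions = unname(regions))
  phases <- lapply(gr, function(g)
    fit_moire_phase(extract_moire_profile(rect, g, spec)))
  crn <- if (corners) detect_checker_corners(frame, det, spec) else NULL
  list(occluded = FALSE, detections = det, phases = phases, corners = crn,
       H = rect$H)
}
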