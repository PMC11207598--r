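#' Moire grating pair
#'
#' A pair of printed line gratings with slightly different spatial
#' frequencies, separated by a transparent substrate of thickness \code{d}
#' and refractive index \code{n_refractive}. Overlaying the two produces a
#' low-frequency beat ("moire") pattern whose phase shifts strongly under
#' small through-plane rotations: a viewing ray refracts through the
#' substrate, so tilting the pair displaces the depth-separated grating
#' relative to the other, advancing the beat phase. The rotation/phase law
#' implemented by [rotation_from_phase()] is
#' \deqn{\theta = n \sin(\arctan(\varphi / (2\pi f_1 d)))}
#' with \eqn{\theta} in radians, \eqn{\varphi} the beat phase in radians,
#' \eqn{f_1} the frequency of the depth-separated print (lines/mm) and
#' \eqn{d} the layer separation (mm).
#'
#' The default parameters follow the fabricated marker: fine pairs at
#' 3 and 2.8 lines/mm, coarse pairs at 1.7 and 1.6 lines/mm, a 10 mm
#' substrate, and a polycarbonate refractive index of 1.585 (the material
#' is stated, its index is not; it is therefore a configurable field).
#'
#' @param f_front spatial frequency of the \eqn{f_1} print (lines/mm);
#'   must exceed \code{f_back}.
#' @param f_back spatial frequency of the second print (lines/mm).
#' @param d layer separation / substrate thickness (mm).
#' @param n_refractive substrate refractive index (>= 1).
#' @param axis which through-plane rotation the pair senses:
#'   \code{"pitch"} (profile runs along marker Y) or \code{"yaw"}
#'   (profile along marker X).
#' @param grade \code{"fine"} or \code{"coarse"}.
#' @param region numeric \code{c(xmin, xmax, ymin, ymax)} rectangle on the
#'   marker face (mm, marker frame).
#' @return object of class \code{moire_grating_pair}.
#' @export
moire_grating_pair <- function(f_front, f_back, d = 10, n_refractive = 1.585,
                               axis = c("yaw", "pitch"),
                               grade = c("fine", "coarse"),
                               region = c(-16, 16, 13, 21)) {
  axis <- match.arg(axis)
  grade <- match.arg(grade)
  stopifnot(length(region) == 4)
  if (!(is.finite(f_front) && is.finite(f_back) && f_front > f_back && f_back > 0))
    stop("moire_grating_pair: need f_front > f_back > 0")
  if (!(d > 0)) stop("moire_grating_pair: substrate thickness d must be > 0")
  if (!(n_refractive >= 1)) stop("moire_grating_pair: refractive index must be >= 1")
  if (region[1] >= region[2] || region[3] >= region[4])
    stop("moire_grating_pair: degenerate region")
  structure(list(f_front = f_front, f_back = f_back, d = d,
                 n_refractive = n_refractive, axis = axis, grade = grade,
                 region = as.numeric(region)),
            class = "moire_grating_pair")
}

#' Beat frequency of a grating pair
#'
#' The spatial frequency of the moire envelope, \code{f_front - f_back},
#' in lines/mm on the marker face.
#'
#' @param grating a [moire_grating_pair()].
#' @export
beat_frequency <- function(grating) grating$f_front - grating$f_back

#' Moire phase to physical rotation
#'
#' Converts a moire beat-phase shift to the through-plane rotation that
#' produced it: \code{theta = n * sin(atan(phi / (2*pi*f1*d)))}, returned
#' in degrees. The function is odd and strictly increasing in \code{phase}.
#'
#' @param phase beat-phase shift in radians.
#' @param grating a [moire_grating_pair()].
#' @return rotation angle in degrees.
#' @export
rotation_from_phase <- function(phase, grating) {
  if (!all(is.finite(phase))) stop("rotation_from_phase: non-finite phase")
  theta_rad <- grating$n_refractive *
    sin(atan(phase / (2 * pi * grating$f_front * grating$d)))
  theta_rad * 180 / pi
}

#' Physical rotation to moire phase
#'
#' Exact algebraic inverse of [rotation_from_phase()]:
#' \code{phi = 2*pi*f1*d * tan(asin(theta_rad / n))}. Defined for
#' \code{|theta_rad / n| < 1}.
#'
#' @param angle rotation in degrees.
#' @param grating a [moire_grating_pair()].
#' @return beat-phase shift in radians.
#' @export
phase_from_rotation <- function(angle, grating) {
  theta_rad <- angle * pi / 180
  r <- theta_rad / grating$n_refractive
  if (any(abs(r) >= 1))
    stop("phase_from_rotation: angle outside invertible domain (|theta_rad| >= n)")
  2 * pi * grating$f_front * grating$d * tan(asin(r))
}

#' Phase-wrap rotation of a grating pair
#'
#' The rotation at which the moire beat phase completes a full cycle
#' (2*pi) and becomes ambiguous; equals
#' \code{rotation_from_phase(2*pi, grating)}. Fine pairs wrap sooner than
#' coarse pairs, which is why each axis carries one of each: the fine
#' channel provides sensitivity, the coarse channel dynamic range.
#'
#' @param grating a [moire_grating_pair()].
#' @return wrap angle in degrees.
#' @export
phase_wrap_rotation <- function(grating) {
  rotation_from_phase(2 * pi, grating)
}

# ---------------------------------------------------------------------------
# anchor (ArUco-style) dictionary

# rotate a 4x4 logical bit matrix 90 degrees clockwise
rotate_bits <- function(m) t(m[nrow(m):1, , drop = FALSE])

code_to_bits <- function(code) {
  matrix(bitwAnd(bitwShiftR(as.integer(code), 0:15), 1L) == 1L,
         nrow = 4, byrow = TRUE)
}

bits_to_code <- function(m) {
  sum(as.integer(t(m)) * 2L^(0:15))
}

#' Anchor code dictionary
#'
#' Deterministically generates \code{n} 4x4 binary identification codes
#' for the square anchor fiducials, with the properties required for
#' reliable decoding: no code is rotation-symmetric, and every pair of
#' codes (over all four 90-degree rotations of each) differs in at least
#' \code{min_dist} of the 16 bits. The same scan order always yields the
#' same dictionary.
#'
#' @param n number of codes.
#' @param min_dist minimum Hamming distance between any two oriented codes.
#' @return integer vector of codes (row-major bit packing, bit 0 = top-left).
#' @export
aruco_dictionary <- function(n = 4, min_dist = 4) {
  chosen <- integer(0)
  chosen_rots <- list()
  for (code in seq(0L, 65535L)) {
    b <- code_to_bits(code)
    nb <- sum(b)
    if (nb < 5 || nb > 11) next               # avoid near-uniform patterns
    rots <- list(b, rotate_bits(b), rotate_bits(rotate_bits(b)),
                 rotate_bits(rotate_bits(rotate_bits(b))))
    rcodes <- vapply(rots, bits_to_code, 0)
    if (length(unique(rcodes)) < 4) next      # rotation symmetric
    # distance between own rotations (orientation must be decodable)
    ok <- TRUE
    for (i in 1:3) for (j in (i + 1):4)
      if (sum(xor(rots[[i]], rots[[j]])) < min_dist) ok <- FALSE
    if (!ok) next
    for (prev in chosen_rots) {
      for (ri in rots) for (pj in prev)
        if (sum(xor(ri, pj)) < min_dist) { ok <- FALSE; break }
      if (!ok) break
    }
    if (!ok) next
    chosen <- c(chosen, code)
    chosen_rots <- c(chosen_rots, list(rots))
    if (length(chosen) == n) break
  }
  if (length(chosen) < n) stop("aruco_dictionary: could not find enough codes")
  chosen
}

#' Anchor cell pattern
#'
#' Expands an anchor code to its printed 6x6 cell pattern: a one-cell
#' black border surrounding the 4x4 identification grid. 0 = black,
#' 1 = white; rows run top to bottom on the marker face.
#'
#' @param code integer code from [aruco_dictionary()].
#' @return 6x6 numeric matrix of cell values.
#' @export
aruco_pattern <- function(code) {
  m <- matrix(0, 6, 6)
  m[2:5, 2:5] <- code_to_bits(code) * 1
  m
}

# ---------------------------------------------------------------------------
# marker specification

#' Marker specification
#'
#' Geometry of the fiducial marker face: a central checkerboard (in-plane
#' DOF via PnP, depth via stereo DLT), four corner anchor squares used to
#' localise the face, and four moire grating pairs (fine + coarse for each
#' of pitch and yaw). All coordinates are in the marker frame (mm, origin
#' at the checkerboard centre, X right, Y up).
#'
#' The default layout fills about 80% of the 76 x 58 mm field of view of
#' the external tracking cameras: a 61 x 46 mm face, an 8 x 6 square
#' checkerboard with 4 mm squares, 9 mm anchors in the corners, yaw
#' gratings above/below the checkerboard and pitch gratings to its sides.
#'
#' @param checkerboard list with \code{rows}, \code{cols} (square counts)
#'   and \code{square} (mm).
#' @param aruco_anchors list of four entries \code{list(id, center, size)}
#'   with distinct ids; corner coordinates are derived.
#' @param gratings list of four [moire_grating_pair()]s covering
#'   fine/coarse x pitch/yaw.
#' @param face_size numeric \code{c(width, height)} (mm).
#' @return object of class \code{marker_spec}.
#' @export
marker_spec <- function(checkerboard = list(rows = 6, cols = 8, square = 4),
                        aruco_anchors = NULL,
                        gratings = NULL,
                        face_size = c(61, 46)) {
  if (is.null(aruco_anchors)) {
    ids <- aruco_dictionary(4)
    cx <- 24.5; cy <- 17.5
    centers <- list(c(-cx, cy), c(cx, cy), c(cx, -cy), c(-cx, -cy))
    aruco_anchors <- lapply(1:4, function(i)
      list(id = ids[i], center = centers[[i]], size = 9))
  }
  if (is.null(gratings)) {
    gratings <- list(
      yaw_fine = moire_grating_pair(3, 2.8, axis = "yaw", grade = "fine",
                                    region = c(-16, 16, 13, 21)),
      yaw_coarse = moire_grating_pair(1.7, 1.6, axis = "yaw", grade = "coarse",
                                      region = c(-16, 16, -21, -13)),
      pitch_fine = moire_grating_pair(3, 2.8, axis = "pitch", grade = "fine",
                                      region = c(20, 28, -12, 12)),
      pitch_coarse = moire_grating_pair(1.7, 1.6, axis = "pitch",
                                        grade = "coarse",
                                        region = c(-28, -20, -12, 12))
    )
  }
  spec <- structure(list(checkerboard = checkerboard,
                         aruco_anchors = aruco_anchors,
                         gratings = gratings,
                         face_size = as.numeric(face_size)),
                    class = "marker_spec")
  validate_marker_spec(spec)
  spec
}

validate_marker_spec <- function(spec) {
  ids <- vapply(spec$aruco_anchors, function(a) a$id, 0)
  if (length(ids) != 4 || anyDuplicated(ids))
    stop("marker_spec: exactly 4 distinct anchor ids required")
  hw <- spec$face_size[1] / 2; hh <- spec$face_size[2] / 2
  cb <- checkerboard_extent(spec)
  for (g in spec$gratings) {
    r <- g$region
    if (r[2] > cb[1] && r[1] < cb[2] && r[4] > cb[3] && r[3] < cb[4])
      stop("marker_spec: grating region overlaps the checkerboard")
    if (r[1] < -hw || r[2] > hw || r[3] < -hh || r[4] > hh)
      stop("marker_spec: grating region outside the marker face")
  }
  for (a in spec$aruco_anchors) {
    s <- a$size / 2
    if (abs(a$center[1]) + s > hw || abs(a$center[2]) + s > hh)
      stop("marker_spec: anchor outside the marker face")
  }
  invisible(spec)
}

# checkerboard bounding box c(xmin, xmax, ymin, ymax) in marker mm
checkerboard_extent <- function(spec) {
  w <- spec$checkerboard$cols * spec$checkerboard$square
  h <- spec$checkerboard$rows * spec$checkerboard$square
  c(-w / 2, w / 2, -h / 2, h / 2)
}

#' Ideal checkerboard inner-corner coordinates
#'
#' Inner corners of the marker checkerboard in the marker frame, ordered
#' row-major from the top-left corner (as seen on the face), Z = 0.
#'
#' @param spec a [marker_spec()] (or a calibration board via
#'   \code{board = TRUE} semantics elsewhere).
#' @return (rows-1)*(cols-1) x 3 matrix of mm coordinates.
#' @export
checkerboard_corners <- function(spec) {
  cb <- spec$checkerboard
  ext <- checkerboard_extent(spec)
  xs <- ext[1] + cb$square * seq_len(cb$cols - 1)
  ys <- ext[4] - cb$square * seq_len(cb$rows - 1)
  g <- expand.grid(x = xs, y = ys)            # row-major from top-left
  cbind(g$x, g$y, 0)
}

#' Anchor corner coordinates
#'
#' The four outer corners of each anchor square in the marker frame,
#' ordered top-left, top-right, bottom-right, bottom-left (as seen on the
#' face), Z = 0.
#'
#' @param spec a [marker_spec()].
#' @return named list (by anchor id) of 4 x 3 matrices (mm).
#' @export
anchor_corners <- function(spec) {
  out <- lapply(spec$aruco_anchors, function(a) {
    s <- a$size / 2; c0 <- a$center
    m <- rbind(c(-s, s), c(s, s), c(s, -s), c(-s, -s))
    cbind(sweep(m, 2, -c0), 0)
  })
  names(out) <- vapply(spec$aruco_anchors, function(a) as.character(a$id), "")
  out
}

#' Read and write marker specifications
#'
#' Lossless YAML serialisation of a [marker_spec()].
#'
#' @param spec a \code{marker_spec}.
#' @param path file path.
#' @return \code{read_marker_spec} returns a \code{marker_spec}.
#' @export
write_marker_spec <- function(spec, path) {
  x <- list(
    schema = "moirepose/marker_spec/1",
    checkerboard = spec$checkerboard,
    face_size = spec$face_size,
    aruco_anchors = lapply(spec$aruco_anchors, function(a)
      list(id = a$id, center = a$center, size = a$size)),
    gratings = lapply(spec$gratings, function(g)
      list(f_front = g$f_front, f_back = g$f_back, d = g$d,
           n_refractive = g$n_refractive, axis = g$axis, grade = g$grade,
           region = g$region))
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_marker_spec
#' @export
read_marker_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, "moirepose/marker_spec/1"))
    stop("read_marker_spec: unrecognised schema in ", path)
  gr <- lapply(x$gratings, function(g)
    moire_grating_pair(g$f_front, g$f_back, g$d, g$n_refractive,
                       axis = g$axis, grade = g$grade, region = g$region))
  names(gr) <- names(x$gratings)
  marker_spec(checkerboard = x$checkerboard,
              aruco_anchors = lapply(x$aruco_anchors, function(a)
                list(id = a$id, center = as.numeric(a$center), size = a$size)),
              gratings = gr,
              face_size = as.numeric(x$face_size))
}

# fetch the fine/coarse pair for one axis
gratings_for_axis <- function(spec, axis) {
  g <- spec$gratings
  list(fine = g[[paste0(axis, "_fine")]], coarse = g[[paste0(axis, "_coarse")]])
}
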