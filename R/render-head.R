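# Procedural head proxy: a deterministic, textured ellipsoid stand-in
# for a rendered human head, used to exercise the markerless pose
# regressor without external 3-D assets.

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Head-proxy parameters
#'
#' A procedural head model: an ellipsoid (half axes within human head
#' bounds) carrying a seeded smooth 3-D texture (sum of sinusoids in the
#' head-local frame) and fixed facial landmarks (eye sockets, nose,
#' mouth) as Gaussian surface features. Deterministic given the seed;
#' different seeds give visibly different "heads" (shape jitter, texture
#' pattern, base skin tone) for unseen-head generalisation tests.
#'
#' @param seed texture/shape seed.
#' @param axes base ellipsoid half axes (mm): lateral, vertical,
#'   anterior.
#' @param base_level base skin grey level.
#' @param n_tex number of texture components.
#' @return object of class \code{head_proxy_params}.
#' @export
head_proxy_params <- function(seed = 1, axes = c(75, 110, 90),
                              base_level = 175, n_tex = 24) {
  stopifnot(all(axes > 40), all(axes < 160))
  with_seed(seed, {
    ax <- axes * (1 + 0.06 * runif(3, -1, 1))
    base <- base_level * (1 + 0.08 * runif(1, -1, 1))
    dir <- matrix(rnorm(3 * n_tex), n_tex)
    dir <- dir / sqrt(rowSums(dir^2))
    # two texture bands: broad shading variation plus near-pixel-scale
    # detail (skin texture, hair) -- real faces carry contrast at both
    # scales, and the fine band is what encodes sub-pixel motion
    kmag <- c(runif(n_tex / 2, 0.1, 0.6), runif(n_tex / 2, 0.8, 3.0))
    amp <- c(runif(n_tex / 2, 0.05, 0.12), runif(n_tex / 2, 0.06, 0.15))
    tex <- cbind(dir * kmag, runif(n_tex, 0, 2 * pi), amp)
    # landmarks scale with the ellipsoid; z solved to sit near the surface
    zs <- function(x, y) ax[3] * sqrt(pmax(0.05, 1 - (x / ax[1])^2 - (y / ax[2])^2))
    mark <- function(fx, fy, r, depth) {
      x <- fx * ax[1]; y <- fy * ax[2]
      c(x, y, zs(x, y), r, depth)
    }
    spots <- rbind(
      mark(-0.40, 0.28, 7, 0.65), mark(0.40, 0.28, 7, 0.65),    # eyes
      mark(-0.42, 0.45, 4, 0.55), mark(0.42, 0.45, 4, 0.55),    # brows
      mark(-0.09, -0.12, 2.5, 0.60), mark(0.09, -0.12, 2.5, 0.60), # nostrils
      mark(0, 0.05, 6, -0.40),                                  # nose bridge
      mark(0, -0.36, 5, 0.55),                                  # mouth
      mark(-0.18, -0.35, 3, 0.50), mark(0.18, -0.35, 3, 0.50),  # corners
      mark(0, -0.52, 4, 0.35),                                  # chin crease
      mark(-0.30, -0.05, 9, -0.25), mark(0.30, -0.05, 9, -0.25),# cheeks
      mark(0, 0.78, 14, 0.55),                                  # hairline
      mark(-0.35, 0.70, 12, 0.50), mark(0.35, 0.70, 12, 0.50)
    )
    structure(list(seed = seed, axes = ax, base_level = base,
                   tex = tex, spots = spots,
                   light = c(0.25, 0.45, 0.86) / sqrt(sum(c(0.25, 0.45, 0.86)^2)),
                   ambient = 0.35, diffuse = 0.65),
              class = "head_proxy_params")
  })
}

#' In-bore camera pair for head views
#'
#' Two in-bore-preset cameras viewing the head from opposing azimuths
#' (left and right of the face), as mounted on the arch over the head
#' coil. World frame = reference head frame (head at origin, face
#' towards +Z).
#'
#' @param distance camera-to-head-centre distance (mm).
#' @param azimuth_deg camera azimuth about the vertical axis (degrees).
#' @param elevation_deg camera elevation (degrees).
#' @return list of two world-to-camera transforms \code{cam1}, \code{cam2}
#'   and the shared \code{intrinsics}.
#' @export
head_camera_rig <- function(distance = 300, azimuth_deg = 35,
                            elevation_deg = 15) {
  pos <- function(az) {
    a <- az * pi / 180; e <- elevation_deg * pi / 180
    distance * c(sin(a) * cos(e), sin(e), cos(a) * cos(e))
  }
  list(cam1 = camera_look_at(pos(azimuth_deg)),
       cam2 = camera_look_at(pos(-azimuth_deg)),
       intrinsics = camera_preset("inbore"))
}

#' Render a head-proxy view
#'
#' Ray-traces the procedural head at a commanded pose through a pinhole
#' camera. Deterministic given parameter and noise seeds. At the in-bore
#' camera scale roughly 4.5 px span a millimetre, so sub-millimetre pose
#' changes move the smooth texture gradients by fractions of a pixel --
#' the signal the pose regressor learns.
#'
#' @param pose commanded [pose6dof()] (head displacement from reference;
#'   bounded to +/- 6 mm / degrees, the simulator's working range).
#' @param camera a [camera_intrinsics()].
#' @param params a [head_proxy_params()].
#' @param opts a [render_options()] (noise and blur are honoured).
#' @param viewing world-to-camera transform (default: camera 1 of
#'   [head_camera_rig()]).
#' @param width,height output size (px); the full 720 x 480 in-bore frame
#'   by default.
#' @param supersample rays per pixel axis.
#' @param timestamp,camera_id frame metadata.
#' @return a [new_frame()].
#' @export
render_head_proxy <- function(pose, camera, params,
                              opts = render_options(blur_sd = 0.6),
                              viewing = NULL,
                              width = camera$resolution[1],
                              height = camera$resolution[2],
                              supersample = 1,
                              timestamp = 0, camera_id = "cam") {
  if (any(abs(unclass(pose)[1:6]) > 6))
    stop("render_head_proxy: pose outside the simulator working range")
  if (is.null(viewing)) viewing <- head_camera_rig()$cam1
  tf <- pose_to_transform(pose)
  sc <- width / camera$resolution[1]
  img <- .render_head_cpp(tf$R, tf$t, viewing$R, viewing$t,
                          camera$fx * sc, camera$fy * sc,
                          camera$cx * sc, camera$cy * sc,
                          as.integer(width), as.integer(height),
                          as.integer(supersample),
                          params$axes, params$tex, params$spots,
                          params$light, params$ambient, params$diffuse,
                          params$base_level, opts$background)
  cam_scaled <- camera
  cam_scaled$cx <- camera$cx * sc; cam_scaled$cy <- camera$cy * sc
  cam_scaled$resolution <- c(width, height)
  img <- post_process_frame(img, cam_scaled, opts)
  new_frame(img, timestamp = timestamp, camera_id = camera_id)
}
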