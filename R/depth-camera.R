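#' Pinhole depth camera specification
#'
#' An ideal structured-light depth camera (Kinect-like): pinhole intrinsics,
#' z-depth readout in millimeters, 0 = invalid. The default resolution and
#' focal length are a 2x-downscaled Kinect-1 depth sensor (640 x 480, f ~ 580
#' px), which keeps desk-scale renders cheap at the same field of view.
#'
#' @param width,height image size in pixels.
#' @param focal_px focal length in pixels (square pixels assumed).
#' @param cx,cy principal point (0-based pixel coordinates).
#' @param pose a [rigid_transform()] mapping camera coordinates to world
#'   (camera +z = optical axis, +x right, +y image-down), e.g. [look_at()].
#' @return object of class `depth_camera`.
#' @export
depth_camera <- function(width = 320L, height = 240L, focal_px = 290,
                         cx = (width - 1) / 2, cy = (height - 1) / 2,
                         pose = look_at(c(0, -700, 0), c(0, 0, 0))) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 focal_px = focal_px, cx = cx, cy = cy, pose = pose),
            class = "depth_camera")
}

#' Render noisy depth frames of a scene
#'
#' Per-pixel first-hit ray casting against the scene primitives, reported as
#' z-depth (distance along the optical axis, mm). Pixels that miss every
#' primitive are invalid (0); so are pixels whose first hit is a
#' `depth_visible = FALSE` primitive (materials the camera cannot range still
#' occlude what is behind them). Each frame adds independent zero-mean
#' Gaussian noise of standard deviation `noise_std` to valid pixels; real
#' Kinect-1 depth shows ~25 mm point-to-plane std at 1 m range.
#'
#' @param sc a [scene()].
#' @param camera a [depth_camera()].
#' @param noise_std depth noise standard deviation (mm), >= 0.
#' @param n_frames number of frames to render, >= 1.
#' @param seed optional integer seed for the noise stream.
#' @return list of `depth_frame` objects: each a list with `depth`
#'   (`width x height` matrix, mm, 0 invalid) and `camera`.
#' @export
render_depth <- function(sc, camera, noise_std = 0, n_frames = 1L,
                         seed = NULL) {
  stopifnot(noise_std >= 0, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  nu <- camera$width; nv <- camera$height
  uu <- rep(seq_len(nu) - 1L, times = nv)
  vv <- rep(seq_len(nv) - 1L, each = nu)
  # camera-frame ray directions (unnormalized z = 1)
  dx <- (uu - camera$cx) / camera$focal_px
  dy <- (vv - camera$cy) / camera$focal_px
  Dc <- cbind(dx, dy, 1)
  nrm <- sqrt(rowSums(Dc * Dc))
  R <- camera$pose$rotation
  Dw <- (Dc / nrm) %*% t(R)
  ow <- camera$pose$translation
  O <- matrix(ow, nrow(Dw), 3, byrow = TRUE)
  t_first <- rep(Inf, nrow(Dw))
  vis_first <- rep(TRUE, nrow(Dw))
  for (prim in sc$primitives) {
    iv <- .ray_interval(prim, O, Dw)
    hit <- iv$t2 > iv$t1 & iv$t1 > 1e-9
    closer <- hit & iv$t1 < t_first
    t_first[closer] <- iv$t1[closer]
    vis_first[closer] <- prim$depth_visible
  }
  zdepth <- ifelse(is.finite(t_first) & vis_first, t_first / nrm, 0)
  base <- matrix(zdepth, nu, nv)
  valid <- base > 0
  lapply(seq_len(n_frames), function(i) {
    d <- base
    if (noise_std > 0)
      d[valid] <- pmax(0.1, d[valid] + stats::rnorm(sum(valid), 0, noise_std))
    structure(list(depth = d, camera = camera), class = "depth_frame")
  })
}

#' Project a world point into the depth image
#'
#' Inverse of [backproject_pixel()] composed with the camera pose; used to
#' derive seed pixels from known sphere centers when emulating the manual
#' marking step.
#'
#' @param camera a [depth_camera()].
#' @param p world point (3-vector) or n x 3 matrix.
#' @return n x 2 matrix of 0-based (u, v) pixel coordinates.
#' @export
project_to_pixel <- function(camera, p) {
  if (is.null(dim(p))) p <- matrix(p, 1)
  pc <- apply_transform(invert_transform(camera$pose), p)
  if (is.null(dim(pc))) pc <- matrix(pc, 1)
  cbind(u = pc[, 1] / pc[, 3] * camera$focal_px + camera$cx,
        v = pc[, 2] / pc[, 3] * camera$focal_px + camera$cy)
}
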