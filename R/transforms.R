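#' Rigid transform between coordinate frames
#'
#' Represents the map `p -> rotation %*% (p - g) + translation`: a translation
#' of the source frame to a fitted origin `g`, followed by a rotation onto the
#' target axes and a final offset between the two origins. This is the form
#' produced by the sphere-scaffold cross-calibration, where `g` is the fitted
#' scaffold origin in camera coordinates and `translation` the known offset
#' between scaffold origin and CT isocenter.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation 3-vector (mm).
#' @param g pre-rotation origin offset (mm), default zero.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            g = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (tolerance 1e-9)")
  if (det(rotation) < 0)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 g = as.numeric(g)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param trans a [rigid_transform()].
#' @param p 3-vector or n x 3 matrix of points.
#' @return transformed points, same shape as `p`.
#' @export
apply_transform <- function(trans, p) {
  if (is.null(dim(p))) {
    drop(trans$rotation %*% (p - trans$g)) + trans$translation
  } else {
    sweep(sweep(p, 2, trans$g) %*% t(trans$rotation), 2,
          trans$translation, `+`)
  }
}

#' Invert a rigid transform
#'
#' @param trans a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(trans) {
  # p' = R (p - g) + t  =>  p = R^T (p' - t) + g
  rigid_transform(t(trans$rotation), trans$g, trans$translation)
}

#' Compose rotation matrix about the z axis
#' @param angle_rad rotation angle (radians), counter-clockwise about +z.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(angle_rad) {
  c <- cos(angle_rad); s <- sin(angle_rad)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Camera pose looking at a target
#'
#' Builds a camera-to-world rigid transform for a pinhole camera at
#' `position` whose optical (+z) axis points at `target`. The camera x axis
#' is chosen horizontal (perpendicular to `up`), y completes the right-handed
#' frame (pointing roughly opposite `up`, i.e. image-down).
#'
#' @param position,target 3-vectors (mm) in world coordinates.
#' @param up approximate world up direction, default +z.
#' @return a [rigid_transform()] mapping camera coordinates to world.
#' @export
look_at <- function(position, target, up = c(0, 0, 1)) {
  zc <- target - position
  zc <- zc / sqrt(sum(zc^2))
  xc <- c(zc[2] * up[3] - zc[3] * up[2],
          zc[3] * up[1] - zc[1] * up[3],
          zc[1] * up[2] - zc[2] * up[1])   # z x up: horizontal right
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-12) stop("view direction parallel to up")
  xc <- xc / nx
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])   # z x x = y (image-down)
  R <- unname(cbind(xc, yc, zc))
  # camera->world: p_w = R p_c + position  ==  R (p_c - 0) + position
  rigid_transform(R, position, c(0, 0, 0))
}
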