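#' Analytic scene primitives
#'
#' Scenes are ordered lists of spheres and finite cylinders with additive
#' linear attenuation; they stand in for both the CT object (water bottles,
#' dense rods, calibration cylinder) and the surfaces the depth camera sees.
#' `depth_visible = FALSE` marks materials the structured-light camera cannot
#' range (IR-dark or specular dense rods, transparent rods): rays whose first
#' hit is such a primitive return invalid depth.
#'
#' @param center sphere center / cylinder axis anchor, 3-vector (mm).
#' @param radius radius (mm), > 0.
#' @param attenuation linear attenuation (1/mm), >= 0.
#' @param depth_visible does the depth camera see this surface?
#' @param label optional label carried into segmentation output.
#' @return a `primitive` list.
#' @export
sphere_primitive <- function(center, radius, attenuation = 0.02,
                             depth_visible = TRUE, label = "sphere") {
  stopifnot(radius > 0, attenuation >= 0)
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = radius, attenuation = attenuation,
                 depth_visible = depth_visible, label = label),
            class = "primitive")
}

#' @rdname sphere_primitive
#' @param axis cylinder axis direction (need not be unit).
#' @param half_length half of the cylinder length (mm).
#' @export
cylinder_primitive <- function(center, radius, half_length,
                               axis = c(0, 0, 1), attenuation = 0.02,
                               depth_visible = TRUE, label = "cylinder") {
  stopifnot(radius > 0, half_length > 0, attenuation >= 0)
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = "cylinder", center = as.numeric(center),
                 radius = radius, half_length = half_length, axis = axis,
                 attenuation = attenuation, depth_visible = depth_visible,
                 label = label),
            class = "primitive")
}

#' Build a scene from primitives
#'
#' @param ... primitives, or a single list of primitives.
#' @return object of class `scene` (attenuations of overlapping primitives
#'   add).
#' @export
scene <- function(...) {
  prims <- list(...)
  if (length(prims) == 1L && !inherits(prims[[1]], "primitive"))
    prims <- prims[[1]]
  if (!length(prims)) stop("scene needs at least one primitive")
  if (!all(vapply(prims, inherits, TRUE, "primitive")))
    stop("all scene members must be primitives")
  structure(list(primitives = prims), class = "scene")
}

#' Sphere-scaffold calibration phantom
#'
#' A z-aligned cylinder (the CT-side calibration phantom acting as mount)
#' with three orthogonal rods carrying 2-4 spheres each; the spheres sit
#' exactly on the coordinate axes at the given offsets and the scaffold
#' origin coincides with the cylinder center, so the fitted scaffold frame
#' is the CT frame.
#'
#' @param sphere_layout named list `x`, `y`, `z` of on-axis center offsets
#'   (mm), 2-4 per axis.
#' @param sphere_radius sphere radius (mm).
#' @param cylinder_radius,cylinder_halflen mount cylinder dimensions (mm).
#' @param attenuation attenuation given to every primitive (1/mm); the
#'   calibration scan is depth-only so this is cosmetic.
#' @return a `scene`; sphere primitives are labeled `"<axis><order>"`
#'   (e.g. `"x1"`, `"x2"`, ...), inner to outer.
#' @export
make_calibration_scene <- function(sphere_layout = list(x = c(80, 140, 200),
                                                        y = c(80, 140, 200),
                                                        z = c(80, 140, 200)),
                                   sphere_radius = 20,
                                   cylinder_radius = 25,
                                   cylinder_halflen = 25,
                                   attenuation = 0.02) {
  axes <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  for (ax in c("x", "y", "z")) {
    n <- length(sphere_layout[[ax]])
    if (is.null(n) || n < 2L || n > 4L)
      stop("each axis needs 2 to 4 spheres; axis '", ax, "' has ",
           if (is.null(n)) 0 else n)
  }
  prims <- list(cylinder_primitive(c(0, 0, 0), cylinder_radius,
                                   cylinder_halflen,
                                   attenuation = attenuation,
                                   label = "mount"))
  for (ax in c("x", "y", "z")) {
    offs <- sort(sphere_layout[[ax]])
    for (i in seq_along(offs)) {
      prims[[length(prims) + 1L]] <-
        sphere_primitive(axes[[ax]] * offs[i], sphere_radius,
                         attenuation = attenuation,
                         label = paste0(ax, i))
    }
  }
  # validity: no two spheres overlap
  cs <- t(vapply(prims[-1], `[[`, numeric(3), "center"))
  if (nrow(cs) > 1) {
    d <- as.matrix(stats::dist(cs))
    diag(d) <- Inf
    if (min(d) <= 2 * sphere_radius)
      stop("invalid layout: spheres overlap")
  }
  scene(prims)
}

#' Two-cylinder knee phantom
#'
#' Two z-aligned water-attenuation cylinders ("knees") separated along x,
#' with two dense rods in the gap between them standing in for bone. The
#' rods are `depth_visible = FALSE` (dense IR-dark material the depth camera
#' cannot range). The scene is mirror-symmetric about the x = 0 plane.
#'
#' @param cyl_radius bottle radius (mm).
#' @param cyl_separation center-to-center distance along x (mm); must exceed
#'   `2 * cyl_radius`.
#' @param cyl_halflen bottle half length (mm).
#' @param rod_radius,rod_halflen rod dimensions (mm).
#' @param rod_offset rod center distance from x = 0 (mm).
#' @param mu_water water attenuation (1/mm).
#' @param rod_attenuation_scale rod attenuation as a multiple of water.
#' @return a `scene` (bottles labeled `"kneeL"`, `"kneeR"`; rods `"rod1"`,
#'   `"rod2"`).
#' @export
make_knee_scene <- function(cyl_radius = 36, cyl_separation = 112,
                            cyl_halflen = 120,
                            rod_radius = 5, rod_halflen = 120,
                            rod_offset = 8,
                            mu_water = 0.02, rod_attenuation_scale = 10) {
  stopifnot(cyl_radius > 0, rod_radius > 0, cyl_halflen > 0)
  if (cyl_separation <= 2 * cyl_radius)
    stop("invalid layout: cylinders intersect")
  h <- cyl_separation / 2
  scene(
    cylinder_primitive(c(-h, 0, 0), cyl_radius, cyl_halflen,
                       attenuation = mu_water, label = "kneeL"),
    cylinder_primitive(c(+h, 0, 0), cyl_radius, cyl_halflen,
                       attenuation = mu_water, label = "kneeR"),
    cylinder_primitive(c(-rod_offset, 0, 0), rod_radius, rod_halflen,
                       attenuation = rod_attenuation_scale * mu_water,
                       depth_visible = FALSE, label = "rod1"),
    cylinder_primitive(c(+rod_offset, 0, 0), rod_radius, rod_halflen,
                       attenuation = rod_attenuation_scale * mu_water,
                       depth_visible = FALSE, label = "rod2")
  )
}
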