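#' Cone-beam scan geometry
#'
#' Describes a circular short-scan cone-beam acquisition: an X-ray source and
#' a flat-panel detector rotating rigidly about the z axis, with the detector
#' centered on the principal ray. Distances are millimeters, angles degrees.
#'
#' The default values correspond to a clinical C-arm setup: source-detector
#' distance 1200 mm, source-axis distance 600 mm, 133 views over a 200 deg
#' short scan, and a 1240 x 960 panel with 0.308 mm pixel pitch. `downscale`
#' shrinks the detector grid by an integer factor while keeping the physical
#' aperture (cols and rows divided, pitch multiplied), which is how desk-scale
#' simulations are run.
#'
#' @param sdd_mm source-to-detector distance (mm).
#' @param sad_mm source-to-rotation-axis distance (mm).
#' @param n_angles number of projection angles (end-inclusive sampling).
#' @param angular_range_deg total scan range in degrees, in (0, 360].
#' @param det_cols,det_rows detector grid size in pixels (u, v).
#' @param pitch_u_mm,pitch_v_mm detector pixel pitch (mm/pixel).
#' @param downscale integer detector downscaling factor (see Details).
#' @return object of class `cone_beam_geometry`.
#' @examples
#' g <- cone_beam_geometry(downscale = 10)
#' g$det_cols  # 124
#' @export
cone_beam_geometry <- function(sdd_mm = 1200, sad_mm = 600,
                               n_angles = 133L, angular_range_deg = 200,
                               det_cols = 1240L, det_rows = 960L,
                               pitch_u_mm = 0.308, pitch_v_mm = 0.308,
                               downscale = 1L) {
  downscale <- as.integer(downscale)
  stopifnot(downscale >= 1L)
  if (downscale > 1L) {
    det_cols <- as.integer(round(det_cols / downscale))
    det_rows <- as.integer(round(det_rows / downscale))
    pitch_u_mm <- pitch_u_mm * downscale
    pitch_v_mm <- pitch_v_mm * downscale
  }
  if (!(sdd_mm > sad_mm && sad_mm > 0))
    stop("need sdd_mm > sad_mm > 0")
  if (n_angles < 2L) stop("n_angles must be >= 2")
  if (!(angular_range_deg > 0 && angular_range_deg <= 360))
    stop("angular_range_deg must be in (0, 360]")
  structure(list(
    sdd_mm = sdd_mm, sad_mm = sad_mm,
    n_angles = as.integer(n_angles),
    angular_range_deg = angular_range_deg,
    det_cols = as.integer(det_cols), det_rows = as.integer(det_rows),
    pitch_u_mm = pitch_u_mm, pitch_v_mm = pitch_v_mm,
    rotation_axis = c(0, 0, 1)
  ), class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf(
    "cone-beam geometry: SDD %.6g mm, SAD %.6g mm, %d views over %.6g deg\n",
    x$sdd_mm, x$sad_mm, x$n_angles, x$angular_range_deg))
  cat(sprintf("  detector %d x %d px @ %.4g x %.4g mm\n",
              x$det_cols, x$det_rows, x$pitch_u_mm, x$pitch_v_mm))
  invisible(x)
}

#' Projection angles of a scan
#'
#' End-inclusive sampling of `[0, angular_range]`: step = range/(n-1), so a
#' 200 deg scan with 133 views has a 200/132 ~ 1.515 deg step.
#'
#' @param geom a [cone_beam_geometry()].
#' @return numeric vector of angles in radians, length `n_angles`.
#' @export
scan_angles <- function(geom) {
  seq(0, geom$angular_range_deg, length.out = geom$n_angles) * pi / 180
}

.check_angle_index <- function(geom, angle_index) {
  if (any(angle_index < 0L) || any(angle_index >= geom$n_angles))
    stop("angle_index out of range [0, n_angles)")
}

#' X-ray source position at a view
#'
#' The source moves on a circle of radius `sad_mm` in the plane z = 0,
#' starting on the +x axis at view 0 and rotating counter-clockwise about +z.
#'
#' @param geom a [cone_beam_geometry()].
#' @param angle_index 0-based view index.
#' @return 3-vector (mm).
#' @export
source_position <- function(geom, angle_index) {
  .check_angle_index(geom, angle_index)
  beta <- scan_angles(geom)[angle_index + 1L]
  geom$sad_mm * c(cos(beta), sin(beta), 0)
}

#' Detector frame at a view
#'
#' Returns the detector center and in-plane unit axes for one view. The
#' detector sits opposite the source at distance `sdd_mm`, centered on the
#' principal ray (the source-origin line); `eu` is parallel to the scan
#' plane, `ev` parallel to the rotation axis (+z).
#'
#' @inheritParams source_position
#' @return list with `source`, `center`, `eu`, `ev` (3-vectors, mm).
#' @export
detector_frame <- function(geom, angle_index) {
  .check_angle_index(geom, angle_index)
  beta <- scan_angles(geom)[angle_index + 1L]
  s <- geom$sad_mm * c(cos(beta), sin(beta), 0)
  dir_c <- -c(cos(beta), sin(beta), 0)          # principal ray direction
  center <- s + geom$sdd_mm * dir_c
  eu <- c(-sin(beta), cos(beta), 0)             # in scan plane
  ev <- c(0, 0, 1)                              # along rotation axis
  list(source = s, center = center, eu = eu, ev = ev)
}

#' Physical detector-pixel center positions
#'
#' 0-based pixel coordinates; pixel (u, v) center offset from the detector
#' center is `(u - (cols-1)/2) * pitch_u` along `eu` and likewise along `ev`.
#'
#' @inheritParams source_position
#' @param u,v 0-based pixel indices (vectors allowed, recycled).
#' @return n x 3 matrix of positions (mm).
#' @export
pixel_position <- function(geom, angle_index, u, v) {
  fr <- detector_frame(geom, angle_index)
  du <- (u - (geom$det_cols - 1) / 2) * geom$pitch_u_mm
  dv <- (v - (geom$det_rows - 1) / 2) * geom$pitch_v_mm
  n <- max(length(du), length(dv))
  du <- rep_len(du, n); dv <- rep_len(dv, n)
  t(fr$center + outer(fr$eu, du) + outer(fr$ev, dv))
}

#' Ray from source through a detector pixel
#'
#' @inheritParams pixel_position
#' @return list with `origin` (3-vector) and `direction` (unit 3-vector).
#' @export
ray_for_pixel <- function(geom, angle_index, u, v) {
  if (u < 0 || u > geom$det_cols - 1 || v < 0 || v > geom$det_rows - 1)
    stop("pixel outside detector grid")
  p <- drop(pixel_position(geom, angle_index, u, v))
  s <- source_position(geom, angle_index)
  d <- p - s
  list(origin = s, direction = d / sqrt(sum(d^2)))
}

#' Read / write a scan geometry as a plain-text config
#'
#' Keys: `sdd_mm, sad_mm, n_angles, angular_range_deg, det_cols, det_rows,
#' pitch_u_mm, pitch_v_mm` (YAML, one key per line).
#'
#' @param path file path.
#' @return `read_geometry_config` returns a [cone_beam_geometry()].
#' @export
read_geometry_config <- function(path) {
  cf <- yaml::read_yaml(path)
  need <- c("sdd_mm", "sad_mm", "n_angles", "angular_range_deg",
            "det_cols", "det_rows", "pitch_u_mm", "pitch_v_mm")
  miss <- setdiff(need, names(cf))
  if (length(miss)) stop("geometry config missing keys: ",
                         paste(miss, collapse = ", "))
  cone_beam_geometry(cf$sdd_mm, cf$sad_mm, cf$n_angles, cf$angular_range_deg,
                     cf$det_cols, cf$det_rows, cf$pitch_u_mm, cf$pitch_v_mm)
}

#' @rdname read_geometry_config
#' @param geom a [cone_beam_geometry()].
#' @export
write_geometry_config <- function(geom, path) {
  yaml::write_yaml(geom[c("sdd_mm", "sad_mm", "n_angles", "angular_range_deg",
                          "det_cols", "det_rows", "pitch_u_mm", "pitch_v_mm")],
                   path)
  invisible(path)
}

#' Half fan angle of the detector
#'
#' Largest in-plane ray angle off the principal ray, from the detector
#' half-width: `atan(((cols-1)/2) * pitch_u / sdd)`. Used by the Parker
#' short-scan condition (range >= 180 deg + 2 * fan).
#'
#' @param geom a [cone_beam_geometry()].
#' @return angle in radians.
#' @export
half_fan_angle <- function(geom) {
  atan(((geom$det_cols - 1) / 2) * geom$pitch_u_mm / geom$sdd_mm)
}
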