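#' Least-squares sphere-center fit with known radius
#'
#' Minimizes the geometric residual `sum_i (||p_i - c|| - r)^2` over the
#' center `c` by Gauss-Newton iteration. The radius is taken from the
#' phantom specification rather than fitted: on a partially visible cap the
#' joint center/radius problem is ill-conditioned, while the known-radius
#' problem stays well-posed.
#'
#' The recommended initialization (used by [calibrate_scaffold()]) takes x,
#' y from the clicked pixel's back-projection and z as the mean depth of the
#' segmented points plus half the radius — i.e. it starts behind the visible
#' front surface, which only makes sense for this distance-minus-radius
#' residual.
#'
#' @param cloud a [surface_cloud()] of segmented sphere-surface points.
#' @param radius known sphere radius (mm).
#' @param init initial center guess (3-vector, mm).
#' @param max_iter,tol Gauss-Newton iteration controls.
#' @return list of class `sphere_fit`: `center`, `radius`, `n_points`,
#'   `rms_residual` (mm).
#' @export
fit_sphere_center <- function(cloud, radius, init, max_iter = 100L,
                              tol = 1e-10) {
  P <- cloud$points
  if (nrow(P) < 10L) stop("need at least 10 points for a sphere fit")
  stopifnot(radius > 0, all(is.finite(init)))
  if (max(apply(P, 2, stats::sd)) < 1e-12)
    stop("degenerate point set: all points coincide")
  c_est <- as.numeric(init)
  for (it in seq_len(max_iter)) {
    dv <- sweep(P, 2, c_est, `-`)
    dist <- sqrt(rowSums(dv * dv))
    if (any(dist < 1e-9)) dist <- pmax(dist, 1e-9)
    r_res <- dist - radius            # residuals
    J <- -dv / dist                   # d dist / d c
    g <- crossprod(J, r_res)
    H <- crossprod(J)
    step <- tryCatch(solve(H, g), error = function(e)
      stop("degenerate sphere-fit normal equations"))
    c_est <- c_est - drop(step)
    if (sqrt(sum(step^2)) < tol) break
  }
  if (it == max_iter && sqrt(sum(step^2)) > 1e-6)
    stop(sprintf("sphere fit did not converge (last step %.3g, rms %.3g mm)",
                 sqrt(sum(step^2)), sqrt(mean(r_res^2))))
  dv <- sweep(P, 2, c_est, `-`)
  r_res <- sqrt(rowSums(dv * dv)) - radius
  structure(list(center = unname(as.numeric(c_est)), radius = radius,
                 n_points = nrow(P),
                 rms_residual = sqrt(mean(r_res^2))),
            class = "sphere_fit")
}

#' Fit a scaffold axis through sphere centers
#'
#' Orthogonal distance regression through 2-4 fitted sphere centers: the
#' anchor is the centroid and the direction the first right-singular vector
#' of the centered center matrix (the best-fit line in the total
#' least-squares sense). The sign is fixed by the click order: the direction
#' points from the innermost to the outermost sphere, i.e. away from the
#' scaffold origin.
#'
#' @param centers n x 3 matrix (or list of 3-vectors) of sphere centers,
#'   ordered inner to outer along the rod.
#' @return list of class `axis_estimate`: `anchor`, `direction` (unit),
#'   `n_spheres`, `rms_residual` (mm, point-to-line).
#' @export
estimate_axis <- function(centers) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n < 2L || n > 4L) stop("an axis needs 2 to 4 sphere centers")
  anchor <- colMeans(centers)
  A <- sweep(centers, 2, anchor)
  if (max(abs(A)) < 1e-12) stop("all centers coincide")
  sv <- svd(A)
  v <- sv$v[, 1]
  if (sum((centers[n, ] - centers[1, ]) * v) < 0) v <- -v
  perp <- A - outer(drop(A %*% v), v)
  structure(list(anchor = anchor, direction = v, n_spheres = n,
                 rms_residual = sqrt(mean(rowSums(perp^2)))),
            class = "axis_estimate")
}

#' Closest point to three axes (scaffold origin)
#'
#' Solves the normal equations of `min_g sum_i dist(g, line_i)^2` in closed
#' form: `g = (sum_i (I - v_i v_i^T))^{-1} sum_i (I - v_i v_i^T) a_i`, where
#' `a_i` are anchors and `v_i` unit directions.
#'
#' @param axes list of three `axis_estimate` objects.
#' @return list of class `origin_estimate`: `origin` (3-vector, mm) and
#'   `residual` (RMS point-to-line distance, mm).
#' @export
estimate_origin <- function(axes) {
  if (length(axes) != 3L) stop("need exactly 3 axes")
  M <- matrix(0, 3, 3); rhs <- numeric(3)
  for (ax in axes) {
    Pm <- diag(3) - outer(ax$direction, ax$direction)
    M <- M + Pm
    rhs <- rhs + drop(Pm %*% ax$anchor)
  }
  if (kappa(M) > 1e8)
    stop("degenerate axis configuration (near-parallel axes)")
  g <- drop(solve(M, rhs))
  d2 <- vapply(axes, function(ax) {
    w <- g - ax$anchor
    sum(w^2) - sum(w * ax$direction)^2
  }, 0)
  structure(list(origin = g, residual = sqrt(mean(pmax(d2, 0)))),
            class = "origin_estimate")
}

#' Build the camera-to-CT rigid transform from fitted scaffold geometry
#'
#' The three fitted axis directions (in camera coordinates) are mapped to
#' the CT basis vectors given by `axis_to_ct_map`; the orthonormal rotation
#' closest to that correspondence (orthogonal Procrustes, proper) is
#' combined with the fitted origin `g` and the known scaffold-to-isocenter
#' offset: `p_ct = R (p_cam - g) + t_origins`.
#'
#' @param origin an `origin_estimate`.
#' @param axes named list of three `axis_estimate`s.
#' @param axis_to_ct_map character vector mapping each axis label to a CT
#'   axis, default `c(x = "x", y = "y", z = "z")` (labels follow the
#'   configured click order).
#' @param t_origins translation from scaffold origin to CT isocenter (mm);
#'   0 when the scaffold origin coincides with the phantom center.
#' @return a [rigid_transform()]; attribute `z_rotation_deg` reports the
#'   dominant in-plane rotation component.
#' @export
build_transform <- function(origin, axes,
                            axis_to_ct_map = c(x = "x", y = "y", z = "z"),
                            t_origins = c(0, 0, 0)) {
  ct_basis <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  labs <- names(axes)
  if (is.null(labs) || !all(labs %in% names(axis_to_ct_map)))
    stop("axes must be a named list matching axis_to_ct_map")
  V <- vapply(axes, function(a) a$direction, numeric(3))   # 3 x 3, cols cam
  dots <- crossprod(V)
  diag(dots) <- 0
  if (max(abs(dots)) > 0.2)
    stop("fitted axes far from orthogonal (max |dot| > 0.2)")
  E <- vapply(labs, function(l) ct_basis[[axis_to_ct_map[[l]]]], numeric(3))
  # want R V ~ E  =>  R = closest rotation to E V^T
  M <- E %*% t(V)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  out <- rigid_transform(R, as.numeric(t_origins), origin$origin)
  attr(out, "z_rotation_deg") <- atan2(R[2, 1] - R[1, 2],
                                       R[1, 1] + R[2, 2]) * 180 / pi
  out
}

#' Full scaffold cross-calibration from depth frames
#'
#' Runs the whole camera-side pipeline: denoise the frames
#' ([preprocess_depth()]), grow a region from each seed
#' ([segment_sphere()]), fit each sphere center ([fit_sphere_center()] with
#' the recommended pixel/mean-depth initialization), fit the three axes
#' ([estimate_axis()]), the scaffold origin ([estimate_origin()]) and the
#' rigid transform ([build_transform()]).
#'
#' @param frames list of `depth_frame`s of the calibration phantom.
#' @param seeds data.frame with columns `u`, `v` (0-based seed pixels),
#'   `axis` (`"x"/"y"/"z"`), `order` (on-axis click order, inner to outer).
#' @param sphere_radius known sphere radius (mm).
#' @param t_origins scaffold-origin-to-isocenter offset (mm).
#' @param ... passed to [preprocess_depth()].
#' @return list of class `calibration`: `transform`, `origin`, `axes`,
#'   `sphere_fits`, `frame` (the denoised frame).
#' @export
calibrate_scaffold <- function(frames, seeds, sphere_radius,
                               t_origins = c(0, 0, 0), ...) {
  frame <- preprocess_depth(frames, ...)
  fits <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    sd_i <- seeds[i, ]
    cl <- segment_sphere(frame, c(u = sd_i$u, v = sd_i$v), sphere_radius,
                         label = paste0(sd_i$axis, sd_i$order))
    seed_p <- backproject_pixel(frame, as.integer(round(sd_i$u)),
                                as.integer(round(sd_i$v)))
    init <- c(seed_p[1], seed_p[2],
              mean(cl$points[, 3]) + sphere_radius / 2)
    fits[[i]] <- fit_sphere_center(cl, sphere_radius, init)
    fits[[i]]$axis <- sd_i$axis
    fits[[i]]$order <- sd_i$order
  }
  axes <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
    sel <- fits[vapply(fits, function(f) f$axis == ax, TRUE)]
    if (length(sel) < 2L) stop("axis '", ax, "' has fewer than 2 spheres")
    sel <- sel[order(vapply(sel, `[[`, 0, "order"))]
    estimate_axis(t(vapply(sel, `[[`, numeric(3), "center")))
  })
  org <- estimate_origin(axes)
  tr <- build_transform(org, axes, t_origins = t_origins)
  structure(list(transform = tr, origin = org, axes = axes,
                 sphere_fits = fits, frame = frame),
            class = "calibration")
}

#' Write a calibration report as plain text
#'
#' @param calib a `calibration` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(calib, path) {
  tr <- calib$transform
  rep <- list(
    rotation = lapply(seq_len(3), function(i) as.numeric(tr$rotation[i, ])),
    translation = as.numeric(tr$translation),
    g = as.numeric(tr$g),
    z_rotation_deg = as.numeric(attr(tr, "z_rotation_deg")),
    origin_residual_mm = calib$origin$residual,
    axes = lapply(calib$axes, function(a)
      list(direction = as.numeric(a$direction),
           n_spheres = a$n_spheres,
           rms_residual_mm = a$rms_residual)),
    spheres = lapply(calib$sphere_fits, function(f)
      list(label = paste0(f$axis, f$order), center = as.numeric(f$center),
           n_points = f$n_points, rms_residual_mm = f$rms_residual))
  )
  yaml::write_yaml(rep, path)
  invisible(path)
}

#' Read a calibration report back into a rigid transform
#'
#' @param path file written by [write_calibration_report()].
#' @return a [rigid_transform()].
#' @export
read_calibration_report <- function(path) {
  rep <- yaml::read_yaml(path)
  R <- do.call(rbind, rep$rotation)
  # polish away the text round-trip: nearest proper rotation
  sv <- svd(R)
  R <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  rigid_transform(R, rep$translation, rep$g)
}
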