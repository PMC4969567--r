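## Projection-domain correction of saturated detector rows.
##
## For one view and one detector row, all rays lie in the plane spanned by
## the X-ray source and the row of pixel centers. The (calibrated) surface
## cloud is sliced by that plane, the back side completed by mirroring, one
## closed cubic B-spline fitted per connected cluster, and the per-pixel
## beam-path length through the curves used as the extrapolation template
## for the saturated run.

#' Correction parameters
#'
#' @param k_norm pixels averaged for the normalization value at each segment
#'   end.
#' @param k_skip extra pixels skipped inward before the averaging window,
#'   stepping over the detector's nonlinear roll-off next to the saturated
#'   run.
#' @param band_mm half-thickness of the slicing slab around the row plane.
#'   The default (1.5 mm) covers both the detector row footprint at the
#'   isocenter and the typical depth-camera sample spacing, so a slab always
#'   catches at least one ring of surface samples.
#' @param n_ctrl,smooth closed-spline fit controls ([fit_closed_spline()]).
#' @param linking_mm single-linkage clustering distance separating the two
#'   knees in a slice.
#' @param min_cluster_pts clusters smaller than this are dropped (stray
#'   samples, partial rod sightings).
#' @param mirror complete the unseen back side by mirroring
#'   ([mirror_backside()])? Use FALSE when merged multi-camera clouds
#'   already close the surface.
#' @param n_poly polygon sampling density for curve/ray intersections.
#' @return list of parameters.
#' @export
correction_params <- function(k_norm = 5L, k_skip = 3L, band_mm = 1.5,
                              n_ctrl = 16L, smooth = 1e-2,
                              linking_mm = 25, min_cluster_pts = 6L,
                              mirror = TRUE, n_poly = 256L) {
  list(k_norm = as.integer(k_norm), k_skip = as.integer(k_skip),
       band_mm = band_mm, n_ctrl = as.integer(n_ctrl), smooth = smooth,
       linking_mm = linking_mm, min_cluster_pts = as.integer(min_cluster_pts),
       mirror = mirror, n_poly = as.integer(n_poly))
}

# In-plane frame of the source/row plane: unit normal n, in-plane axes
# e1 ~ global x, e2 with positive global-y component (so "behind" is +y2d).
.row_plane_frame <- function(geom, angle_index, v) {
  s <- source_position(geom, angle_index)
  pp <- pixel_position(geom, angle_index, c(0, geom$det_cols - 1), c(v, v))
  a <- pp[1, ] - s; b <- pp[2, ] - s
  n <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  n <- n / sqrt(sum(n^2))
  e1 <- c(1, 0, 0) - n[1] * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  if (e2[2] < 0) e2 <- -e2
  list(source = s, n = n, e1 = e1, e2 = e2)
}

#' Slice a surface cloud by a detector-row plane
#'
#' Selects cloud points within `band_mm` of the plane through the X-ray
#' source and detector row `v`, and returns their in-plane 2-D coordinates
#' (origin at the source; first axis aligned with global x, second chosen
#' with positive global-y component so mirroring about a line parallel to
#' the x-z plane is a reflection in the second coordinate).
#'
#' @param cloud a [surface_cloud()] in CT coordinates.
#' @param geom a [cone_beam_geometry()].
#' @param angle_index 0-based view index.
#' @param v 0-based detector row.
#' @param band_mm slab half-thickness (mm).
#' @return n x 2 matrix of in-plane coordinates; attribute `frame` holds the
#'   plane frame. Fewer than 6 points in the slab is an error.
#' @export
slice_surface_points <- function(cloud, geom, angle_index, v, band_mm = 1.5) {
  fr <- .row_plane_frame(geom, angle_index, v)
  rel <- sweep(cloud$points, 2, fr$source)
  dist <- drop(rel %*% fr$n)
  sel <- abs(dist) < band_mm
  if (sum(sel) < 6L)
    stop("insufficient points in row-plane slab (", sum(sel), " < 6)")
  pts <- cbind(drop(rel[sel, , drop = FALSE] %*% fr$e1),
               drop(rel[sel, , drop = FALSE] %*% fr$e2))
  attr(pts, "frame") <- fr
  pts
}

#' Mirror the visible front surface to the unseen back side
#'
#' Reflects the points about the line `y = mirror_y` (parallel to the
#' in-plane first axis, i.e. to the world x-z plane) and returns the union.
#' The default mirror height is the deepest visible point (max y), the
#' silhouette rim seen by a single camera.
#'
#' @param points n x 2 in-plane points of one cluster.
#' @param mirror_y mirror line height; default `max(points[, 2])`.
#' @return (2n) x 2 matrix.
#' @export
mirror_backside <- function(points, mirror_y = NULL) {
  points <- as.matrix(points)
  if (!nrow(points)) stop("empty point set")
  if (is.null(mirror_y)) mirror_y <- max(points[, 2])
  rbind(points, cbind(points[, 1], 2 * mirror_y - points[, 2]))
}

#' Cluster a 2-D slice into connected components
#'
#' Single-linkage clustering cut at `linking_mm`; clusters below
#' `min_pts` are discarded.
#'
#' @param points n x 2 matrix.
#' @param linking_mm linkage distance (mm).
#' @param min_pts minimum cluster size.
#' @param max_points subsample bound (keeps slice clustering cheap).
#' @return list of point matrices, largest first.
#' @export
cluster_slice <- function(points, linking_mm = 25, min_pts = 6L,
                          max_points = 600L) {
  points <- as.matrix(points)
  if (nrow(points) > max_points) {
    keep <- seq(1L, nrow(points), length.out = max_points)
    points <- points[unique(as.integer(keep)), , drop = FALSE]
  }
  if (nrow(points) == 1L) return(list())
  hc <- stats::hclust(stats::dist(points), method = "single")
  grp <- stats::cutree(hc, h = linking_mm)
  out <- lapply(split(seq_along(grp), grp), function(ix)
    points[ix, , drop = FALSE])
  out <- out[vapply(out, nrow, 0L) >= min_pts]
  out[order(-vapply(out, nrow, 0L))]
}

#' Per-pixel beam-path lengths through the surface curves of one row
#'
#' @param curves list of `surface_curve`s in the row-plane coordinates.
#' @param frame row-plane frame (attribute of [slice_surface_points()]).
#' @param geom,angle_index,v row identification as in
#'   [slice_surface_points()].
#' @param n_poly polygon sampling density.
#' @return numeric vector of lengths (mm), one per detector column; 0 where
#'   the ray misses every curve.
#' @export
row_intersection_profile <- function(curves, frame, geom, angle_index, v,
                                     n_poly = 256L) {
  nu <- geom$det_cols
  P <- pixel_position(geom, angle_index, seq_len(nu) - 1L, rep(v, nu))
  rel <- sweep(P, 2, frame$source)
  dirs <- cbind(drop(rel %*% frame$e1), drop(rel %*% frame$e2))
  dirs <- dirs / sqrt(rowSums(dirs * dirs))
  profile <- numeric(nu)
  for (cv in curves) {
    poly <- spline_polygon(cv, n_poly)
    profile <- profile + .profile_against_polygon(dirs, poly)
  }
  profile
}

# Interior lengths of rays from the origin along `dirs` (n x 2, unit)
# through one polygon; vectorized over rays x edges.
.profile_against_polygon <- function(dirs, poly) {
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  wx <- a[, 1]; wy <- a[, 2]                  # ray origin is (0, 0)
  den <- outer(dirs[, 1], ey) - outer(dirs[, 2], ex)        # rays x edges
  s <- (outer(dirs[, 2], wx) - outer(dirs[, 1], wy)) / den
  tt <- (matrix(wx * ey - wy * ex, nrow(dirs), n, byrow = TRUE)) / den
  keep <- abs(den) > 1e-12 & s >= 0 & s < 1
  out <- numeric(nrow(dirs))
  hit_rows <- which(rowSums(keep) >= 2L)
  for (i in hit_rows) {
    ts <- sort(tt[i, keep[i, ]])
    k <- seq(1L, 2L * (length(ts) %/% 2L), by = 2L)
    out[i] <- sum(ts[k + 1L] - ts[k])
  }
  out
}

#' Locate saturated runs in one detector row
#'
#' Finds maximal saturated runs from the mask. Each segment reports the
#' flanking reliable pixels `x1`, `x2` (0-based; NA when the run touches the
#' detector edge) and a normalization value at each available end: the mean
#' recorded value over the `k_norm` unsaturated pixels ending `k_skip`
#' pixels inward of the flank (the skip steps over the preprocessing
#' roll-off). The averaging window is clipped to unsaturated pixels.
#'
#' @param values numeric vector of recorded row values.
#' @param mask logical vector of saturated pixels.
#' @param k_norm,k_skip see [correction_params()].
#' @return list with `segments` (data.frame: x1, x2, nv1, nv2, w1a, w1b,
#'   w2a, w2b -- 0-based window bounds, NA when one-sided) and
#'   `uncorrectable` (TRUE when the entire row is saturated).
#' @export
detect_saturation <- function(values, mask, k_norm = 5L, k_skip = 3L) {
  stopifnot(length(values) == length(mask))
  n <- length(values)
  if (all(mask)) {
    return(list(segments = .empty_segments(), uncorrectable = TRUE))
  }
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  segs <- .empty_segments()
  for (k in runs) {
    i1 <- starts[k]; i2 <- ends[k]              # 1-based saturated run
    x1 <- if (i1 > 1L) i1 - 2L else NA_integer_ # 0-based flanks
    x2 <- if (i2 < n) i2 else NA_integer_
    win <- function(x, dirn) {
      if (is.na(x)) return(c(NA_integer_, NA_integer_))
      # walk inward (away from the run) over unsaturated pixels
      hi <- x - dirn * k_skip
      lo <- hi - dirn * (k_norm - 1L)
      rng <- sort(c(lo, hi))
      rng <- pmin(pmax(rng, 0L), n - 1L)
      idx <- seq(rng[1], rng[2])
      idx <- idx[!mask[idx + 1L]]
      if (!length(idx)) return(c(x, x))
      c(min(idx), max(idx))
    }
    w1 <- win(x1, +1L)   # left flank: window lies at smaller indices
    w2 <- win(x2, -1L)   # right flank: window lies at larger indices
    nv1 <- if (is.na(x1)) NA_real_ else mean(values[seq(w1[1], w1[2]) + 1L])
    nv2 <- if (is.na(x2)) NA_real_ else mean(values[seq(w2[1], w2[2]) + 1L])
    segs <- rbind(segs, data.frame(x1 = x1, x2 = x2, nv1 = nv1, nv2 = nv2,
                                   w1a = w1[1], w1b = w1[2],
                                   w2a = w2[1], w2b = w2[2]))
  }
  list(segments = segs, uncorrectable = FALSE)
}

.empty_segments <- function() {
  data.frame(x1 = integer(), x2 = integer(), nv1 = numeric(),
             nv2 = numeric(), w1a = integer(), w1b = integer(),
             w2a = integer(), w2b = integer())
}

#' Extrapolate one detector row across its saturated runs
#'
#' Within each saturated run, the recorded value at pixel x is replaced by
#' `s(x) * profile(x)`, where the scale `s(x)` blends linearly between the
#' two end scales. Each end scale is the ratio of the normalization value to
#' the mean beam-path length over the same averaging window, so the scale is
#' an effective attenuation estimated where the data are reliable. One-sided
#' (edge-touching) runs use the single available scale. Pixels whose ray
#' misses the surface model (`profile == 0`) become 0; unsaturated pixels
#' are never modified.
#'
#' @param values recorded row values.
#' @param segments segment table from [detect_saturation()].
#' @param profile per-pixel beam-path lengths
#'   ([row_intersection_profile()]).
#' @return list with `values` (corrected row) and `flags` (character vector
#'   of per-segment notes: "ok", "skipped_zero_profile", "one_sided").
#' @export
correct_row <- function(values, segments, profile) {
  out <- values
  flags <- character(nrow(segments))
  if (!nrow(segments)) return(list(values = out, flags = flags))
  stopifnot(length(profile) == length(values))
  n <- length(values)
  for (i in seq_len(nrow(segments))) {
    sg <- segments[i, ]
    lo0 <- if (is.na(sg$x1)) 0L else sg$x1 + 1L
    hi0 <- if (is.na(sg$x2)) n - 1L else sg$x2 - 1L
    pmax_seg <- if (lo0 <= hi0) max(profile[(lo0:hi0) + 1L]) else 0
    scale_at <- function(nv, wa, wb) {
      if (is.na(nv)) return(NA_real_)
      pm <- mean(profile[seq(wa, wb) + 1L])
      # the anchoring window must have a modeled path comparable to the
      # segment it scales; a near-zero anchor only amplifies model error
      if (pm < max(1, 0.2 * pmax_seg)) return(if (nv > 1e-6) -1 else 0)
      nv / pm
    }
    s1 <- scale_at(sg$nv1, sg$w1a, sg$w1b)
    s2 <- scale_at(sg$nv2, sg$w2a, sg$w2b)
    bad <- function(s) !is.na(s) && s < 0
    if (bad(s1)) s1 <- NA_real_
    if (bad(s2)) s2 <- NA_real_
    if (is.na(s1) && is.na(s2)) {
      flags[i] <- "skipped_zero_profile"
      next
    }
    lo <- if (is.na(sg$x1)) 0L else sg$x1 + 1L
    hi <- if (is.na(sg$x2)) n - 1L else sg$x2 - 1L
    if (lo > hi) { flags[i] <- "empty"; next }
    xs <- lo:hi
    if (is.na(s1) || is.na(s2)) {
      s <- rep(if (is.na(s1)) s2 else s1, length(xs))
      flags[i] <- "one_sided"
    } else {
      w <- (xs - sg$x1) / (sg$x2 - sg$x1)
      s <- (1 - w) * s1 + w * s2
      flags[i] <- "ok"
    }
    out[xs + 1L] <- pmax(0, s * profile[xs + 1L])
  }
  list(values = out, flags = flags)
}

#' Correct a saturated projection stack from a calibrated surface cloud
#'
#' Applies the per-row pipeline (slice, cluster, mirror, closed-spline fit,
#' intersection profile, saturation detection, extrapolation) to every
#' detector row of every view. Rows whose slice fails a precondition (too
#' few surface points, fully saturated) pass through unchanged with a
#' status flag.
#'
#' @param stack a saturated `projection_stack`.
#' @param cloud a [surface_cloud()] already transformed to CT coordinates.
#' @param params a [correction_params()] list.
#' @return list of class `correction_result`: `stack` (corrected
#'   `projection_stack`; mask preserved), `status` (data.frame: angle, row,
#'   n_segments, n_corrected, flag).
#' @export
correct_stack <- function(stack, cloud, params = correction_params()) {
  geom <- stack$geom
  data <- stack$data
  nu <- geom$det_cols; nv <- geom$det_rows; na <- geom$n_angles
  status <- vector("list", na * nv)
  sidx <- 0L
  # coarse z prefilter bounds per cloud
  pz <- cloud$points[, 3]
  for (k in seq_len(na) - 1L) {
    mk <- stack$mask[, , k + 1L]
    rows_todo <- which(colSums(mk) > 0L) - 1L
    for (v in rows_todo) {
      sidx <- sidx + 1L
      res <- tryCatch(
        .correct_one_row(data[, v + 1L, k + 1L], mk[, v + 1L],
                         cloud, geom, k, v, params),
        error = function(e) list(values = NULL, flag = conditionMessage(e),
                                 n_segments = 0L, n_corrected = 0L))
      if (!is.null(res$values))
        data[, v + 1L, k + 1L] <- res$values
      status[[sidx]] <- data.frame(angle = k, row = v,
                                   n_segments = res$n_segments,
                                   n_corrected = res$n_corrected,
                                   flag = res$flag)
    }
  }
  status <- if (sidx) do.call(rbind, status[seq_len(sidx)]) else
    data.frame(angle = integer(), row = integer(), n_segments = integer(),
               n_corrected = integer(), flag = character())
  out <- projection_stack(data, geom, stack$mask)
  structure(list(stack = out, status = status), class = "correction_result")
}

.correct_one_row <- function(values, mask, cloud, geom, angle_index, v,
                             params) {
  det <- detect_saturation(values, mask, params$k_norm, params$k_skip)
  if (det$uncorrectable)
    return(list(values = NULL, flag = "uncorrectable_row",
                n_segments = 0L, n_corrected = 0L))
  if (!nrow(det$segments))
    return(list(values = values, flag = "clean",
                n_segments = 0L, n_corrected = 0L))
  pts <- slice_surface_points(cloud, geom, angle_index, v, params$band_mm)
  frame <- attr(pts, "frame")
  clusters <- cluster_slice(pts, params$linking_mm, params$min_cluster_pts)
  if (!length(clusters))
    return(list(values = NULL, flag = "no_clusters",
                n_segments = nrow(det$segments), n_corrected = 0L))
  curves <- lapply(clusters, function(cl) {
    if (params$mirror) cl <- mirror_backside(cl)
    fit_closed_spline(cl, params$n_ctrl, params$smooth)
  })
  profile <- row_intersection_profile(curves, frame, geom, angle_index, v,
                                      params$n_poly)
  cr <- correct_row(values, det$segments, profile)
  list(values = cr$values,
       flag = paste(cr$flags, collapse = ";"),
       n_segments = nrow(det$segments),
       n_corrected = sum(cr$flags %in% c("ok", "one_sided")))
}
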