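## Depth-frame preprocessing and sphere segmentation.
##
## Invalid pixels (depth 0) are excluded from every average: spatial
## smoothing uses mask-normalized convolution, so values never bleed across
## the valid/invalid border and fully-invalid pixels stay invalid.

# Mask-normalized 2-D convolution (kernel k, zero boundary).
.masked_filter <- function(img, valid, k) {
  num <- EBImage::filter2(img * valid, k, boundary = 0)
  den <- EBImage::filter2(valid * 1, k, boundary = 0)
  out <- ifelse(den > 1e-12, num / den, 0)
  out * valid
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# Range-weighted Gaussian (bilateral) smoothing of a depth image: spatial
# Gaussian of sd sigma_px, range Gaussian of sd sigma_range. Invalid pixels
# carry zero weight. Reduces to the plain masked Gaussian where the surface
# is smooth relative to sigma_range; across true depth discontinuities
# (object rims) the range kernel suppresses mixing.
.bilateral_depth <- function(img, valid, sigma_px, sigma_range) {
  r <- max(1L, ceiling(3 * sigma_px))
  g <- stats::dnorm(-r:r, sd = sigma_px)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  spw <- g[offs$dx + r + 1] * g[offs$dy + r + 1]
  nx <- nrow(img); ny <- ncol(img)
  num <- matrix(0, nx, ny); den <- matrix(0, nx, ny)
  v <- valid * 1
  for (m in seq_len(nrow(offs))) {
    dx <- offs$dx[m]; dy <- offs$dy[m]
    sx <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
    sy <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
    nb <- img[sx, sy]; nv <- v[sx, sy]
    # clamp-at-border duplicates the border pixel; drop those duplicates
    if (dx != 0) nv[if (dx > 0) nx - seq_len(dx) + 1L else seq_len(-dx), ] <- 0
    if (dy != 0) nv[, if (dy > 0) ny - seq_len(dy) + 1L else seq_len(-dy)] <- 0
    w <- spw[m] * nv * exp(-(nb - img)^2 / (2 * sigma_range^2))
    num <- num + w * nb
    den <- den + w
  }
  ifelse(valid & den > 1e-12, num / den, 0)
}

# Mask-normalized box mean with radius r (via integral images).
.box_mean <- function(img, valid, r) {
  cs <- function(m) {
    m <- apply(m, 2, cumsum)
    t(apply(m, 1, cumsum))
  }
  nx <- nrow(img); ny <- ncol(img)
  pad <- function(m) {
    out <- matrix(0, nx + 1, ny + 1)
    out[-1, -1] <- cs(m)
    out
  }
  S <- pad(img * valid); N <- pad(valid * 1)
  ix1 <- pmax(seq_len(nx) - r, 1); ix2 <- pmin(seq_len(nx) + r, nx)
  iy1 <- pmax(seq_len(ny) - r, 1); iy2 <- pmin(seq_len(ny) + r, ny)
  win <- function(M) {
    M[ix2 + 1, iy2 + 1, drop = FALSE] - M[ix1, iy2 + 1, drop = FALSE] -
      M[ix2 + 1, iy1, drop = FALSE] + M[ix1, iy1, drop = FALSE]
  }
  s <- win(S); n <- win(N)
  ifelse(n > 0, s / n, 0)
}

# Self-guided guided filter (He et al. form) restricted to valid pixels.
.guided_filter_self <- function(img, valid, radius, eps) {
  m1 <- .box_mean(img, valid, radius)
  m2 <- .box_mean(img * img, valid, radius)
  v <- pmax(m2 - m1 * m1, 0)
  a <- v / (v + eps)
  b <- (1 - a) * m1
  am <- .box_mean(a, valid, radius)
  bm <- .box_mean(b, valid, radius)
  (am * img + bm) * valid
}

#' Denoise a stack of depth frames
#'
#' Temporal averaging over valid samples per pixel (up to `n_avg` frames),
#' then Gaussian spatial smoothing (sigma `sigma_px`), then edge-preserving
#' guided filtering with the smoothed depth as its own guide. Pixels invalid
#' in every frame remain invalid (0); all averages exclude invalid samples.
#'
#' The spatial stages are noise-adaptive. The per-pixel temporal standard
#' deviation over the frames estimates the sensor noise; when it is
#' negligible (below `noise_floor_mm`) the spatial stages are skipped --
#' spatial smoothing of clean curved depth only flattens it (it biases
#' sphere caps backward), so there is nothing to gain. With a single frame
#' no estimate exists and the spatial stages always run. The Gaussian stage
#' is range-weighted (bilateral, range scale `3 x` the post-averaging noise
#' estimate): across true depth discontinuities such as object rims,
#' where plain convolution would drag surface points toward the camera, the
#' range kernel suppresses mixing, while on smooth regions it reduces to
#' the plain Gaussian kernel.
#'
#' @param frames list of `depth_frame` objects of identical shape, from
#'   [render_depth()].
#' @param sigma_px Gaussian smoothing sigma in pixels.
#' @param n_avg number of frames averaged (frames beyond `n_avg` ignored).
#' @param guide_radius_px guided-filter box radius (pixels of support).
#' @param guide_eps guided-filter regularization (mm^2); variance scales
#'   below it are smoothed, above it (true depth edges, object rims)
#'   preserved. Default NULL: `(3 x post-averaging noise)^2`, so only
#'   noise-scale variation is smoothed and steep rims are left in place.
#' @param noise_floor_mm estimated temporal noise below which the spatial
#'   stages are skipped.
#' @return a single denoised `depth_frame`; attribute `noise_est_mm` holds
#'   the temporal noise estimate (NA for a single frame).
#' @export
preprocess_depth <- function(frames, sigma_px = 2.5, n_avg = 20L,
                             guide_radius_px = 4L, guide_eps = NULL,
                             noise_floor_mm = 0.05) {
  if (!length(frames)) stop("empty frame list")
  frames <- frames[seq_len(min(length(frames), n_avg))]
  dims <- dim(frames[[1]]$depth)
  if (!all(vapply(frames, function(f) all(dim(f$depth) == dims), TRUE)))
    stop("frames differ in shape")
  acc <- matrix(0, dims[1], dims[2]); acc2 <- matrix(0, dims[1], dims[2])
  cnt <- matrix(0, dims[1], dims[2])
  for (f in frames) {
    v <- f$depth > 0
    acc <- acc + f$depth * v
    acc2 <- acc2 + f$depth^2 * v
    cnt <- cnt + v
  }
  avg <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  valid <- cnt > 0
  multi <- cnt >= 2
  noise_est <- if (any(multi)) {
    vv <- (acc2[multi] - cnt[multi] * avg[multi]^2) / (cnt[multi] - 1)
    sqrt(max(stats::median(vv), 0))
  } else NA_real_
  out <- avg
  if (is.na(noise_est) || noise_est > noise_floor_mm) {
    post_sd <- if (is.na(noise_est)) 25 / sqrt(20) else
      noise_est / sqrt(max(stats::median(cnt[valid]), 1))
    post_sd <- max(post_sd, 0.5)
    if (is.null(guide_eps)) guide_eps <- (3 * post_sd)^2
    out <- .bilateral_depth(out, valid, sigma_px, 3 * post_sd)
    out <- .guided_filter_self(out, valid, guide_radius_px, guide_eps)
  }
  structure(list(depth = out, camera = frames[[1]]$camera,
                 noise_est_mm = noise_est),
            class = "depth_frame")
}

#' Back-project depth pixels to camera coordinates
#'
#' Pinhole model: pixel (u, v) with depth z maps to
#' `((u-cx)/f * z, (v-cy)/f * z, z)`.
#'
#' @param frame a `depth_frame`.
#' @param u,v 0-based pixel coordinates (vectors allowed).
#' @return 3-vector, or n x 3 matrix for vector input.
#' @export
backproject_pixel <- function(frame, u, v) {
  cam <- frame$camera
  z <- frame$depth[cbind(u + 1L, v + 1L)]
  if (any(z <= 0)) stop("invalid depth at requested pixel(s)")
  out <- unname(cbind((u - cam$cx) / cam$focal_px * z,
                      (v - cam$cy) / cam$focal_px * z,
                      z))
  if (nrow(out) == 1L) drop(out) else out
}

#' Back-project every valid pixel of a frame
#'
#' @param frame a `depth_frame`.
#' @param label label attached to the resulting cloud.
#' @return a [surface_cloud()] in camera coordinates.
#' @export
backproject_frame <- function(frame, label = "object surface") {
  idx <- which(frame$depth > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("frame has no valid pixels")
  surface_cloud(backproject_pixel(frame, idx[, 1] - 1L, idx[, 2] - 1L),
                label = label)
}

#' Labeled 3-D surface point set
#'
#' @param points n x 3 matrix of finite points (mm).
#' @param label which sphere/axis or `"object surface"`.
#' @return object of class `surface_cloud`.
#' @export
surface_cloud <- function(points, label = "object surface") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  structure(list(points = points, label = label), class = "surface_cloud")
}

#' Segment one sphere's surface pixels by region growing
#'
#' Flood fill over 4-connected valid pixels starting at a seed (the emulated
#' manual click): a pixel joins while the 3-D metric distance of its
#' back-projected point to the seed's point stays below
#' `growth_factor * sqrt(2) * sphere_radius` (the seed sits at the front of
#' the sphere; `sqrt(2) * r` is the seed-to-rim distance of the visible cap,
#' and the growth factor adds slack for noise without reaching neighboring
#' spheres).
#'
#' @param frame a denoised `depth_frame`.
#' @param seed list/vector with elements `u`, `v`: 0-based seed pixel.
#' @param sphere_radius known sphere radius (mm).
#' @param growth_factor slack multiplier on the cap extent.
#' @param label label for the returned cloud.
#' @return a [surface_cloud()] of the region's back-projected points, with
#'   attribute `pixels` (n x 2, 0-based) of member pixels.
#' @export
segment_sphere <- function(frame, seed, sphere_radius, growth_factor = 1.2,
                           label = "sphere") {
  u0 <- as.integer(round(seed[["u"]])); v0 <- as.integer(round(seed[["v"]]))
  d <- frame$depth
  nx <- nrow(d); ny <- ncol(d)
  if (u0 < 0 || v0 < 0 || u0 >= nx || v0 >= ny || d[u0 + 1, v0 + 1] <= 0)
    stop("seed pixel has invalid depth")
  p0 <- backproject_pixel(frame, u0, v0)
  tol <- growth_factor * sqrt(2) * sphere_radius
  cam <- frame$camera
  # 3-D distance of every valid pixel to the seed point (vectorized once)
  uu <- matrix(seq_len(nx) - 1L, nx, ny)
  vv <- matrix(seq_len(ny) - 1L, nx, ny, byrow = TRUE)
  px <- (uu - cam$cx) / cam$focal_px * d
  py <- (vv - cam$cy) / cam$focal_px * d
  ok <- d > 0 &
    (px - p0[1])^2 + (py - p0[2])^2 + (d - p0[3])^2 <= tol^2
  # flood fill within `ok`, 4-connectivity
  visited <- matrix(FALSE, nx, ny)
  lin0 <- u0 + 1L + nx * v0
  visited[lin0] <- TRUE
  frontier <- lin0
  while (length(frontier)) {
    i <- ((frontier - 1L) %% nx) + 1L
    j <- ((frontier - 1L) %/% nx) + 1L
    cand <- c(frontier[i > 1] - 1L, frontier[i < nx] + 1L,
              frontier[j > 1] - nx, frontier[j < ny] + nx)
    cand <- unique(cand[ok[cand] & !visited[cand]])
    visited[cand] <- TRUE
    frontier <- cand
  }
  idx <- which(visited, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty region")
  pts <- backproject_pixel(frame, idx[, 1] - 1L, idx[, 2] - 1L)
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  out <- surface_cloud(pts, label = label)
  attr(out, "pixels") <- cbind(u = idx[, 1] - 1L, v = idx[, 2] - 1L)
  out
}
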