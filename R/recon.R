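## Short-scan FDK reconstruction chain: cosine weighting, Parker redundancy
## weighting, Shepp-Logan ramp filtering, voxel-driven backprojection,
## Hounsfield scaling, bilateral smoothing, and ROI statistics.

#' Cosine (cone-beam) pre-weighting
#'
#' Multiplies every pixel by `SDD / sqrt(SDD^2 + u^2 + v^2)` with (u, v) the
#' physical pixel offsets from the principal point.
#'
#' @param stack a `projection_stack`.
#' @return the weighted stack.
#' @export
cosine_weight <- function(stack) {
  geom <- stack$geom
  du <- (seq_len(geom$det_cols) - 1 - (geom$det_cols - 1) / 2) *
    geom$pitch_u_mm
  dv <- (seq_len(geom$det_rows) - 1 - (geom$det_rows - 1) / 2) *
    geom$pitch_v_mm
  w <- geom$sdd_mm / sqrt(geom$sdd_mm^2 + outer(du^2, dv^2, `+`))
  out <- stack$data * array(w, dim(stack$data))
  projection_stack(out, geom, stack$mask)
}

#' Parker short-scan redundancy weights
#'
#' Standard smooth (sin^2 transition) Parker weights for a scan over
#' `pi + 2 * Gamma`, with `Gamma = (range - pi) / 2` the half overscan. A
#' ray at source angle beta and fan angle gamma gets
#' \itemize{
#'   \item `sin^2((pi/4) beta / (Gamma + gamma))` for
#'     `beta <= 2 Gamma + 2 gamma`,
#'   \item 1 in the fully sampled middle,
#'   \item `sin^2((pi/4) (pi + 2 Gamma - beta) / (Gamma - gamma))` for
#'     `beta >= pi + 2 gamma`,
#' }
#' so conjugate rays `(beta, gamma)` and `(beta + pi - 2 gamma, -gamma)`
#' weight to exactly 1. Requires `range >= 180 deg + 2 * fan`.
#'
#' @param stack a `projection_stack`.
#' @return the weighted stack.
#' @export
parker_weight <- function(stack) {
  geom <- stack$geom
  w <- parker_weight_matrix(geom)
  out <- stack$data
  for (k in seq_len(geom$n_angles))
    out[, , k] <- out[, , k] * w[, k]
  projection_stack(out, geom, stack$mask)
}

#' @rdname parker_weight
#' @param geom a [cone_beam_geometry()].
#' @return `parker_weight_matrix`: `det_cols x n_angles` matrix of weights
#'   in [0, 1] (constant along detector rows).
#' @export
parker_weight_matrix <- function(geom) {
  fan <- half_fan_angle(geom)
  range_rad <- geom$angular_range_deg * pi / 180
  if (range_rad < pi + 2 * fan)
    stop("angular range below 180 deg + full fan angle: not a short scan")
  Gam <- (range_rad - pi) / 2
  du <- (seq_len(geom$det_cols) - 1 - (geom$det_cols - 1) / 2) *
    geom$pitch_u_mm
  gam <- atan(du / geom$sdd_mm)
  betas <- scan_angles(geom)
  w <- matrix(1, geom$det_cols, geom$n_angles)
  for (k in seq_along(betas))
    w[, k] <- parker_weight_value(geom, betas[k], gam)
  w
}

#' @rdname parker_weight
#' @param beta source angle(s) in radians, in `[0, range]`.
#' @param gamma fan angle(s) in radians (positive toward the scan start).
#' @return `parker_weight_value`: weights in [0, 1], vectorized over
#'   `beta`/`gamma`.
#' @export
parker_weight_value <- function(geom, beta, gamma) {
  range_rad <- geom$angular_range_deg * pi / 180
  fan <- half_fan_angle(geom)
  if (range_rad < pi + 2 * fan)
    stop("angular range below 180 deg + full fan angle: not a short scan")
  Gam <- (range_rad - pi) / 2
  n <- max(length(beta), length(gamma))
  b <- rep_len(beta, n); g <- rep_len(gamma, n)
  w <- rep(1, n)
  lo <- b < 2 * Gam + 2 * g
  hi <- b > pi + 2 * g
  w[lo] <- sin(pi / 4 * b[lo] / (Gam + g[lo]))^2
  w[hi] <- sin(pi / 4 * (pi + 2 * Gam - b[hi]) / (Gam - g[hi]))^2
  pmin(pmax(w, 0), 1)
}

#' Shepp-Logan ramp kernel
#'
#' Discrete kernel `h[n] = -2 / (pi^2 tau^2 (4 n^2 - 1))`.
#'
#' @param n_taps half-width (kernel covers -n_taps..n_taps).
#' @param tau sample spacing (mm).
#' @return numeric vector of length `2 * n_taps + 1`.
#' @export
shepp_logan_kernel <- function(n_taps, tau) {
  n <- -n_taps:n_taps
  -2 / (pi^2 * tau^2 * (4 * n^2 - 1))
}

#' Row-wise Shepp-Logan ramp filtering
#'
#' Convolves every detector row (u direction) with the Shepp-Logan kernel at
#' the detector pixel pitch, via FFT with zero padding to at least twice the
#' row length, and multiplies by the sample spacing (discrete approximation
#' of the continuous convolution).
#'
#' @param stack a `projection_stack` (already cosine/Parker weighted).
#' @return the filtered stack (values are no longer line integrals).
#' @export
ramp_filter <- function(stack) {
  geom <- stack$geom
  nu <- geom$det_cols
  tau <- geom$pitch_u_mm
  h <- shepp_logan_kernel(nu - 1L, tau)
  L <- stats::nextn(2L * nu, 2)
  hp <- numeric(L)
  hp[seq_len(nu)] <- h[nu:(2L * nu - 1L)]            # causal part
  hp[(L - nu + 2L):L] <- h[1L:(nu - 1L)]             # lags -(nu-1)..-1
  H <- stats::fft(hp)
  out <- stack$data
  nv <- geom$det_rows
  for (k in seq_len(geom$n_angles)) {
    page <- matrix(0, L, nv)
    page[seq_len(nu), ] <- out[, , k]
    Fp <- stats::mvfft(page)
    flt <- Re(stats::mvfft(Fp * H, inverse = TRUE)) / L
    out[, , k] <- flt[seq_len(nu), ] * tau
  }
  projection_stack(out, geom, stack$mask)
}

#' Reconstruction grid specification
#'
#' @param n_x,n_y,n_z voxel counts.
#' @param voxel_mm isotropic voxel spacing (mm).
#' @param center grid center (mm), default the isocenter.
#' @return a `volume_spec` list.
#' @export
volume_spec <- function(n_x = 64L, n_y = 64L, n_z = 64L, voxel_mm = 3,
                        center = c(0, 0, 0)) {
  stopifnot(voxel_mm > 0)
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 n_z = as.integer(n_z), voxel_mm = voxel_mm,
                 center = as.numeric(center)),
            class = "volume_spec")
}

.grid_axis <- function(n, spacing, center) {
  (seq_len(n) - 1 - (n - 1) / 2) * spacing + center
}

#' Voxel-driven FDK backprojection
#'
#' For each voxel and view, the filtered projection is sampled bilinearly at
#' the voxel's detector position and accumulated with the FDK distance
#' weight `SAD * SDD / t^2` (t = source-to-voxel distance along the
#' principal direction) and angular step `range / (n - 1)`.
#'
#' @param stack a filtered `projection_stack`.
#' @param vspec a [volume_spec()].
#' @return object of class `ct_volume`: list with `data`
#'   (`n_x x n_y x n_z` array, 1/mm), `spec`, `unit` (`"mu"`).
#' @export
backproject <- function(stack, vspec) {
  geom <- stack$geom
  xs <- .grid_axis(vspec$n_x, vspec$voxel_mm, vspec$center[1])
  ys <- .grid_axis(vspec$n_y, vspec$voxel_mm, vspec$center[2])
  zs <- .grid_axis(vspec$n_z, vspec$voxel_mm, vspec$center[3])
  fov <- geom$sad_mm * sin(half_fan_angle(geom))
  if (min(abs(xs)) > fov && min(abs(ys)) > fov)
    warning("voxel grid does not intersect the field of view")
  nxy <- vspec$n_x * vspec$n_y
  gx <- rep(xs, times = vspec$n_y)
  gy <- rep(ys, each = vspec$n_x)
  dbeta <- (geom$angular_range_deg * pi / 180) / (geom$n_angles - 1)
  nu <- geom$det_cols; nv <- geom$det_rows
  cu <- (nu - 1) / 2; cv <- (nv - 1) / 2
  vol <- array(0, c(vspec$n_x, vspec$n_y, vspec$n_z))
  betas <- scan_angles(geom)
  for (k in seq_len(geom$n_angles)) {
    b <- betas[k]
    page <- stack$data[, , k]
    # source at SAD*(cos b, sin b); principal direction -(cos b, sin b)
    tdist <- geom$sad_mm - gx * cos(b) - gy * sin(b)   # depth along axis
    upos <- (-gx * sin(b) + gy * cos(b)) * geom$sdd_mm / tdist
    ui <- upos / geom$pitch_u_mm + cu
    w2 <- geom$sad_mm * geom$sdd_mm / tdist^2
    u0 <- floor(ui)
    fu <- ui - u0
    in_u <- u0 >= 0 & u0 < nu - 1 & tdist > 1e-6
    mag <- geom$sdd_mm / tdist
    for (iz in seq_len(vspec$n_z)) {
      vpos <- zs[iz] * mag
      vi <- vpos / geom$pitch_v_mm + cv
      v0 <- floor(vi)
      fv <- vi - v0
      ok <- in_u & v0 >= 0 & v0 < nv - 1
      if (!any(ok)) next
      i00 <- cbind(u0[ok] + 1L, v0[ok] + 1L)
      val <- (1 - fu[ok]) * (1 - fv[ok]) * page[i00] +
        fu[ok] * (1 - fv[ok]) * page[cbind(i00[, 1] + 1L, i00[, 2])] +
        (1 - fu[ok]) * fv[ok] * page[cbind(i00[, 1], i00[, 2] + 1L)] +
        fu[ok] * fv[ok] * page[cbind(i00[, 1] + 1L, i00[, 2] + 1L)]
      acc <- numeric(nxy)
      acc[ok] <- w2[ok] * val
      vol[, , iz] <- vol[, , iz] + matrix(acc, vspec$n_x, vspec$n_y) * dbeta
    }
  }
  structure(list(data = vol, spec = vspec, unit = "mu"), class = "ct_volume")
}

#' Full FDK chain
#'
#' Cosine weighting, Parker weighting, Shepp-Logan ramp filtering and
#' voxel-driven backprojection in one call.
#'
#' @param stack a `projection_stack` of line integrals.
#' @param vspec a [volume_spec()].
#' @return a `ct_volume` in attenuation units (1/mm).
#' @export
fdk_reconstruct <- function(stack, vspec = volume_spec()) {
  backproject(ramp_filter(parker_weight(cosine_weight(stack))), vspec)
}

#' Convert attenuation to Hounsfield units
#'
#' `HU = 1000 (mu - mu_water) / mu_water`.
#'
#' @param vol a `ct_volume` in attenuation units.
#' @param mu_water water attenuation (1/mm), > 0.
#' @return the volume in HU (`unit = "HU"`).
#' @export
to_hounsfield <- function(vol, mu_water = 0.02) {
  stopifnot(mu_water > 0)
  vol$data <- 1000 * (vol$data - mu_water) / mu_water
  vol$unit <- "HU"
  vol
}

#' Per-slice bilateral smoothing
#'
#' Edge-preserving smoothing applied to each axial (z) slice: a `width x
#' width` window with Gaussian spatial weights (sigma = width/4 voxels) and
#' Gaussian range weights of scale `photometric_sigma`.
#'
#' @param vol a `ct_volume` (typically in HU).
#' @param width odd window width in voxels.
#' @param photometric_sigma range kernel scale (same unit as the volume).
#' @return the smoothed volume.
#' @export
bilateral_smooth <- function(vol, width = 5L, photometric_sigma = 500) {
  width <- as.integer(width)
  if (width %% 2L == 0L) stop("width must be odd")
  r <- width %/% 2L
  sp_sig <- width / 4
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  spw <- exp(-(offs$dx^2 + offs$dy^2) / (2 * sp_sig^2))
  d <- vol$data
  nx <- dim(d)[1]; ny <- dim(d)[2]
  out <- d
  for (iz in seq_len(dim(d)[3])) {
    sl <- d[, , iz]
    num <- matrix(0, nx, ny); den <- matrix(0, nx, ny)
    for (m in seq_len(nrow(offs))) {
      dx <- offs$dx[m]; dy <- offs$dy[m]
      sx <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
      sy <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
      nb <- sl[sx, sy]
      w <- spw[m] * exp(-(nb - sl)^2 / (2 * photometric_sigma^2))
      num <- num + w * nb
      den <- den + w
    }
    out[, , iz] <- num / den
  }
  vol$data <- out
  vol
}

#' Circular ROI specification
#'
#' @param slice 0-based z slice index.
#' @param cx,cy ROI center in 0-based voxel coordinates.
#' @param radius ROI radius in voxels.
#' @param label ROI label (1..5 in the standard evaluation layout).
#' @return a `roi_spec` list.
#' @export
roi_spec <- function(slice, cx, cy, radius, label) {
  structure(list(slice = as.integer(slice), cx = cx, cy = cy,
                 radius = radius, label = label), class = "roi_spec")
}

#' ROI statistics of a reconstructed volume
#'
#' Mean, population standard deviation, min and max over the voxels of each
#' circular ROI on its slice.
#'
#' @param vol a `ct_volume`.
#' @param rois list of [roi_spec()]s.
#' @return data.frame with columns ROI, Mean, StdDev, Min, Max.
#' @export
roi_stats <- function(vol, rois) {
  d <- vol$data
  nx <- dim(d)[1]; ny <- dim(d)[2]; nz <- dim(d)[3]
  rows <- lapply(rois, function(r) {
    if (r$slice < 0 || r$slice >= nz ||
        r$cx - r$radius < 0 || r$cx + r$radius > nx - 1 ||
        r$cy - r$radius < 0 || r$cy + r$radius > ny - 1)
      stop("ROI '", r$label, "' out of volume bounds")
    ix <- which(outer((seq_len(nx) - 1 - r$cx)^2,
                      (seq_len(ny) - 1 - r$cy)^2, `+`) <= r$radius^2)
    vals <- d[, , r$slice + 1L][ix]
    data.frame(ROI = r$label, Mean = mean(vals),
               StdDev = sqrt(mean((vals - mean(vals))^2)),
               Min = min(vals), Max = max(vals))
  })
  do.call(rbind, rows)
}
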