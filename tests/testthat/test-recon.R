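test_that("cosine weights match the closed form across the detector", {
  g <- study_geom()
  sc <- scene(sphere_primitive(c(0, 0, 0), 30, 0.02))
  st <- simulate_projections(sc, tiny_geom(3L))
  stw <- cosine_weight(projection_stack(array(1, c(g$det_cols, g$det_rows,
                                                   1)), g))
  # principal-point neighborhood ~ 1 (even grid: nearest pixels)
  cu <- g$det_cols / 2; cv <- g$det_rows / 2
  expect_gt(stw$data[cu, cv, 1], 0.9999)
  # strictly decreasing with |u| at fixed v (past the half-pixel center)
  row <- stw$data[, cv, 1]
  expect_true(all(diff(row[(cu + 1):g$det_cols]) < 0))
  # every corner equals SDD/sqrt(SDD^2+u^2+v^2) evaluated independently
  for (ci in list(c(1, 1), c(g$det_cols, 1), c(1, g$det_rows),
                  c(g$det_cols, g$det_rows))) {
    du <- (ci[1] - 1 - (g$det_cols - 1) / 2) * g$pitch_u_mm
    dv <- (ci[2] - 1 - (g$det_rows - 1) / 2) * g$pitch_v_mm
    expect_equal(stw$data[ci[1], ci[2], 1],
                 1200 / sqrt(1200^2 + du^2 + dv^2), tolerance = 1e-12)
  }
})

test_that("Parker weights: bounds, mid-scan, and conjugate-ray closure", {
  g <- study_geom()
  W <- parker_weight_matrix(g)
  expect_true(all(W >= 0 & W <= 1))
  # central ray at mid-scan has weight 1
  b_mid <- (200 * pi / 180) / 2
  expect_equal(parker_weight_value(g, b_mid, 0), 1)
  # conjugate pairs (beta, gamma) / (beta + pi - 2 gamma, -gamma) sum to 1
  set.seed(12)
  fan <- half_fan_angle(g)
  Gam <- (200 * pi / 180 - pi) / 2
  gam <- runif(1000, -fan, fan)
  bmax <- pmax(2 * Gam + 2 * gam, 0)
  beta <- runif(1000) * bmax
  w1 <- parker_weight_value(g, beta, gam)
  w2 <- parker_weight_value(g, beta + pi - 2 * gam, -gam)
  expect_lt(max(abs(w1 + w2 - 1)), 1e-6)
  # a scan below 180 deg + fan is rejected
  g_bad <- cone_beam_geometry(angular_range_deg = 185, downscale = 10)
  expect_error(parker_weight_matrix(g_bad), "short scan")
})

test_that("Shepp-Logan ramp: kernel value, linearity, DC suppression", {
  tau <- 3.08
  h <- shepp_logan_kernel(5, tau)
  expect_equal(h[6], 2 / (pi^2 * tau^2), tolerance = 1e-12)
  expect_equal(h[7], -2 / (pi^2 * tau^2 * 3), tolerance = 1e-12)
  g <- tiny_geom(2L)
  set.seed(13)
  a <- array(runif(g$det_cols * g$det_rows * 2), c(g$det_cols, g$det_rows, 2))
  b <- array(runif(g$det_cols * g$det_rows * 2), c(g$det_cols, g$det_rows, 2))
  fa <- ramp_filter(projection_stack(a, g))$data
  fb <- ramp_filter(projection_stack(b, g))$data
  fab <- ramp_filter(projection_stack(a + b, g))$data
  expect_equal(fab, fa + fb, tolerance = 1e-9)
  # constant row: response vanishes away from the row ends
  cst <- projection_stack(array(1, c(g$det_cols, g$det_rows, 2)), g)
  fc <- ramp_filter(cst)$data[, 1, 1]
  interior <- fc[20:(g$det_cols - 20)]
  expect_lt(max(abs(interior)), 1e-3)
})

test_that("FDK reconstructs a uniform cylinder quantitatively", {
  vol <- fixture("cyl_recon", function() {
    g <- study_geom()
    sc <- scene(cylinder_primitive(c(0, 0, 0), 60, 120, attenuation = 0.02))
    st <- simulate_projections(sc, g)
    fdk_reconstruct(st, volume_spec(64, 64, 64, 3))
  })
  xs <- (seq_len(64) - 1 - 31.5) * 3
  core <- outer(xs^2, xs^2, `+`) <= 30^2
  mid <- vol$data[, , 32][core]
  expect_lt(abs(mean(mid) - 0.02) / 0.02, 0.07)
  # linearity of the chain (before bilateral filtering)
  g <- tiny_geom(5L)
  sc <- scene(sphere_primitive(c(20, 0, 0), 30, 0.02))
  st <- simulate_projections(sc, g)
  v1 <- fdk_reconstruct(st, volume_spec(16, 16, 8, 6))
  st3 <- projection_stack(3 * st$data, g)
  v3 <- fdk_reconstruct(st3, volume_spec(16, 16, 8, 6))
  expect_equal(v3$data, 3 * v1$data, tolerance = 1e-6)
  # all-zero stack reconstructs to zero
  z <- fdk_reconstruct(projection_stack(array(0, dim(st$data)), g),
                       volume_spec(16, 16, 8, 6))
  expect_true(all(z$data == 0))
})

test_that("a dense rod reconstructs at its true position", {
  g <- study_geom()
  sc <- scene(cylinder_primitive(c(30, -21, 0), 6, 100, attenuation = 0.2))
  st <- simulate_projections(sc, g)
  vol <- fdk_reconstruct(st, volume_spec(64, 64, 8, 3))
  sl <- vol$data[, , 4]
  am <- which(sl == max(sl), arr.ind = TRUE)
  pos <- ((am[1, ] - 1) - 31.5) * 3
  expect_lt(max(abs(pos - c(30, -21))), 3)   # within one voxel
})

test_that("Hounsfield conversion is the affine water normalization", {
  v <- structure(list(data = array(c(0.02, 0, 0.04, 0.03), c(2, 2, 1)),
                      spec = volume_spec(2, 2, 1, 1), unit = "mu"),
                 class = "ct_volume")
  hu <- to_hounsfield(v, 0.02)
  expect_equal(as.numeric(hu$data), c(0, -1000, 1000, 500))
  expect_error(to_hounsfield(v, 0), "mu_water")
})

test_that("bilateral filter smooths noise but preserves strong edges", {
  set.seed(5)
  base <- array(0, c(40, 40, 3))
  base[21:40, , ] <- 2000                      # 2000 HU step edge
  noisy <- base + array(rnorm(4800, 0, 100), c(40, 40, 3))
  v <- structure(list(data = noisy, spec = volume_spec(40, 40, 3, 1),
                      unit = "HU"), class = "ct_volume")
  sm <- bilateral_smooth(v, 5, 500)
  # flat-region noise reduced by at least 2x
  expect_lt(sd(sm$data[5:16, 5:36, 2]), sd(noisy[5:16, 5:36, 2]) / 2)
  # edge midpoint stays put: half-max crossing within 1 voxel of 20/21
  prof <- rowMeans(sm$data[, , 2])
  cross <- which(prof > 1000)[1]
  expect_lte(abs(cross - 21), 1)
  # constant volume unchanged
  cv <- structure(list(data = array(7, c(8, 8, 2)),
                       spec = volume_spec(8, 8, 2, 1), unit = "HU"),
                  class = "ct_volume")
  expect_equal(bilateral_smooth(cv, 5, 500)$data, cv$data, tolerance = 1e-9)
  expect_error(bilateral_smooth(cv, 4, 500), "odd")
})

test_that("ROI statistics: constant, two-voxel hand check, bounds", {
  v <- structure(list(data = array(100, c(20, 20, 3)),
                      spec = volume_spec(20, 20, 3, 1), unit = "HU"),
                 class = "ct_volume")
  s <- roi_stats(v, list(roi_spec(1, 10, 10, 3, 1)))
  expect_equal(unlist(s[1, c("Mean", "StdDev", "Min", "Max")]),
               c(Mean = 100, StdDev = 0, Min = 100, Max = 100))
  # two-voxel ROI {-100, 100}: population std = 100
  v$data[10, 10, 2] <- -100
  v$data[11, 10, 2] <- 100
  s2 <- roi_stats(v, list(roi_spec(1, 9.5, 9, 0.71, "pair")))
  expect_equal(unlist(s2[1, c("Mean", "StdDev", "Min", "Max")]),
               c(Mean = 0, StdDev = 100, Min = -100, Max = 100))
  expect_error(roi_stats(v, list(roi_spec(1, 1, 1, 5, "oob"))), "bounds")
})
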