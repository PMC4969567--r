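test_that("analytic line integrals match closed forms and a quadrature oracle", {
  sph <- scene(sphere_primitive(c(10, -5, 3), 25, 0.03))
  # miss
  expect_equal(analytic_line_integral(sph, list(origin = c(200, 0, 0),
                                                direction = c(0, 0, 1))), 0)
  # diameter chord: 2 r mu
  li <- analytic_line_integral(sph, list(origin = c(10, -5, -100),
                                         direction = c(0, 0, 1)))
  expect_equal(li, 2 * 25 * 0.03, tolerance = 1e-12)
  # offset cylinder chord vs ray-marching quadrature oracle
  cyl <- scene(cylinder_primitive(c(0, 0, 0), 30, 60, attenuation = 0.02))
  d <- 12
  ray <- list(origin = c(d, -100, 5), direction = c(0, 1, 0))
  expect_equal(analytic_line_integral(cyl, ray),
               2 * sqrt(30^2 - d^2) * 0.02, tolerance = 1e-12)
  # quadrature oracle: march the ray at 1e-3 mm steps, sum mu inside
  step <- 1e-3
  ts <- seq(0, 200, by = step)
  pts_x <- d; pts_y <- -100 + ts
  inside <- pts_x^2 + pts_y^2 <= 30^2    # z = 5 within the slab
  oracle <- sum(inside) * step * 0.02
  expect_equal(analytic_line_integral(cyl, ray), oracle, tolerance = 1e-3)
})

test_that("line integrals are additive and reparameterization-invariant", {
  sc <- scene(sphere_primitive(c(0, 0, 0), 20, 0.05),
              cylinder_primitive(c(10, 0, 0), 15, 50, attenuation = 0.01))
  ray <- list(origin = c(-5, -200, 2), direction = c(0.05, 1, 0.01))
  ray$direction <- ray$direction / sqrt(sum(ray$direction^2))
  both <- analytic_line_integral(sc, ray)
  p1 <- analytic_line_integral(scene(sc$primitives[[1]]), ray)
  p2 <- analytic_line_integral(scene(sc$primitives[[2]]), ray)
  expect_equal(both, p1 + p2, tolerance = 1e-12)
  # shifting the origin along the ray changes nothing
  ray2 <- list(origin = ray$origin + 37.3 * ray$direction,
               direction = ray$direction)
  expect_equal(analytic_line_integral(sc, ray2), both, tolerance = 1e-12)
})

test_that("simulated projections: symmetry and principal-ray maximum", {
  # odd detector grid so one pixel center sits on the principal ray
  g <- cone_beam_geometry(n_angles = 5L, det_cols = 61L, det_rows = 47L,
                          pitch_u_mm = 6.16, pitch_v_mm = 6.16)
  sc <- scene(sphere_primitive(c(0, 0, 0), 40, 0.02))
  st <- simulate_projections(sc, g)
  # centered sphere: all views identical
  for (k in 2:5)
    expect_equal(st$data[, , k], st$data[, , 1], tolerance = 1e-9)
  # detector max equals the diameter line integral (principal ray)
  expect_equal(max(st$data), 2 * 40 * 0.02, tolerance = 1e-9)
  # empty attenuation scene projects to zero
  st0 <- simulate_projections(scene(sphere_primitive(c(0, 0, 0), 40, 0)), g)
  expect_true(all(st0$data == 0))
  expect_false(any(st0$mask))
})

test_that("saturation model clips, rolls off, and is idempotent", {
  g <- tiny_geom(3L)
  sc <- scene(cylinder_primitive(c(0, 0, 0), 40, 80, attenuation = 0.02))
  st <- simulate_projections(sc, g)
  sat <- apply_saturation(st, p_sat = 0.8, rolloff_width = 0.2)
  # mask equals thresholding the unclipped stack
  expect_equal(sat$mask, st$data < 0.8)
  expect_true(all(sat$data[sat$mask] == 0))
  # untouched above the roll-off band
  high <- st$data >= 1.0
  expect_equal(sat$data[high], st$data[high])
  # roll-off compresses toward p_sat, monotonically, never increasing
  zone <- !sat$mask & st$data < 1.0
  expect_true(all(sat$data[zone] <= st$data[zone] + 1e-12))
  expect_true(all(sat$data[zone] >= 0.8))
  expect_true(all(sat$data <= st$data + 1e-12))
  # idempotent under the same model
  sat2 <- apply_saturation(sat, p_sat = 0.8, rolloff_width = 0.2)
  expect_identical(sat2$data, sat$data)
  expect_identical(sat2$mask, sat$mask)
})

test_that("depth rendering: first hit, misses, noise statistics", {
  cam <- depth_camera(width = 64L, height = 48L, focal_px = 60,
                      pose = look_at(c(0, -700, 0), c(0, 0, 0)))
  sc <- scene(sphere_primitive(c(0, 0, 0), 50, 0.02))
  fr <- render_depth(sc, cam, 0, 1)[[1]]
  cx <- round(cam$cx); cy <- round(cam$cy)
  expect_equal(fr$depth[cx + 1, cy + 1], 700 - 50, tolerance = 0.5)
  expect_identical(fr$depth[1, 1], 0)        # background invalid
  # noiseless rendering is deterministic
  fr2 <- render_depth(sc, cam, 0, 1)[[1]]
  expect_identical(fr$depth, fr2$depth)
  # per-pixel std over 200 frames approximates noise_std within 15%
  frames <- render_depth(sc, cam, 10, 200, seed = 99)
  stack <- sapply(frames, function(f) f$depth[cx + 1, cy + 1])
  expect_lt(abs(sd(stack) - 10) / 10, 0.15)
})

test_that("side-on cylinder depth matches the d - sqrt(r^2 - x^2) profile", {
  cam <- depth_camera(width = 129L, height = 9L, focal_px = 200,
                      pose = look_at(c(0, -700, 0), c(0, 0, 0)))
  r <- 40
  sc <- scene(cylinder_primitive(c(0, 0, 0), r, 100, attenuation = 0.02))
  fr <- render_depth(sc, cam, 0, 1)[[1]]
  row <- fr$depth[, round(cam$cy) + 1]
  us <- which(row > 0) - 1
  # ray-march oracle at 1e-4 steps for a few pixels
  for (u in us[c(10, 30, 64)]) {
    dx <- (u - cam$cx) / cam$focal_px
    dirw <- c(dx, 1, 0) / sqrt(1 + dx^2)
    tt <- seq(600, 720, by = 1e-4)
    px <- -700 * 0 + tt * dirw[1]; py <- -700 + tt * dirw[2]
    hit <- which(px^2 + py^2 <= r^2)[1]
    z_oracle <- tt[hit] / sqrt(1 + dx^2)     # z-depth of first hit
    expect_equal(row[u + 1], z_oracle, tolerance = 1e-3)
  }
})

test_that("phantom constructors validate their layouts", {
  sc <- make_calibration_scene()
  labs <- vapply(sc$primitives, `[[`, "", "label")
  expect_equal(sum(grepl("^[xyz][0-9]$", labs)), 9L)
  # each sphere center has exactly one nonzero coordinate
  for (p in sc$primitives[-1])
    expect_equal(sum(abs(p$center) > 1e-12), 1L)
  expect_error(make_calibration_scene(list(x = 100, y = c(80, 140),
                                           z = c(80, 140))), "2 to 4")
  expect_error(make_calibration_scene(list(x = c(80, 110), y = c(80, 140),
                                           z = c(80, 140)),
                                      sphere_radius = 20), "overlap")
  expect_error(make_knee_scene(cyl_radius = 60, cyl_separation = 100),
               "intersect")
  # knee scene: ray through one bottle's diameter
  knee <- make_knee_scene()
  li <- analytic_line_integral(knee, list(origin = c(-56, -500, 0),
                                          direction = c(0, 1, 0)))
  expect_equal(li, 2 * 36 * 0.02, tolerance = 1e-9)
  # mirror symmetry about x = 0: with the source on the y axis the detector
  # u axis is anti-parallel to x, so every row must be palindromic
  g <- cone_beam_geometry(n_angles = 3L, angular_range_deg = 180,
                          downscale = 20L)
  st <- simulate_projections(knee, g)
  page <- st$data[, , 2]                         # beta = 90 deg
  expect_equal(page, page[rev(seq_len(nrow(page))), ], tolerance = 1e-9)
})
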