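test_that("sphere fit recovers exact and noisy partial-cap centers", {
  set.seed(41)
  truth <- c(10, -5, 700)
  P <- sphere_points(200, truth, 20)
  fit <- fit_sphere_center(surface_cloud(P), 20, truth + c(3, -2, 8))
  expect_equal(fit$center, truth, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-8)
  expect_equal(fit$n_points, 200L)

  # upper-hemisphere cap + 2 mm noise: within 1 mm of truth and matching a
  # coarse-to-fine grid-search oracle to 0.01 mm resolution
  set.seed(1)
  Pc <- sphere_points(500, truth, 20, cap_axis = c(0, 0, -1), cap_cos = 0)
  Pc <- Pc + matrix(rnorm(1500, 0, 2), 500, 3)
  fit2 <- fit_sphere_center(surface_cloud(Pc), 20, truth + c(2, 2, 5))
  expect_lt(sqrt(sum((fit2$center - truth)^2)), 1)
  obj <- function(cc) {
    d <- sqrt((Pc[, 1] - cc[1])^2 + (Pc[, 2] - cc[2])^2 +
              (Pc[, 3] - cc[3])^2) - 20
    sum(d^2)
  }
  best <- fit2$center
  for (hw in c(5, 1, 0.2, 0.05)) {
    gr <- as.matrix(expand.grid(x = seq(-hw, hw, length.out = 11),
                                y = seq(-hw, hw, length.out = 11),
                                z = seq(-hw, hw, length.out = 11)))
    vals <- apply(sweep(gr, 2, best, `+`), 1, obj)
    best <- best + gr[which.min(vals), ]
  }
  expect_lt(sqrt(sum((fit2$center - best)^2)), 0.05)

  # degenerate inputs
  expect_error(fit_sphere_center(surface_cloud(P[1:5, ]), 20, truth),
               "at least 10")
  same <- matrix(rep(c(1, 2, 3), each = 12), 12, 3)
  expect_error(fit_sphere_center(surface_cloud(same), 20, c(0, 0, 0)),
               "degenerate")
})

test_that("axis estimation matches two-point, collinear, and ODR oracles", {
  a <- estimate_axis(rbind(c(0, 0, 0), c(0, 0, 100)))
  expect_equal(a$anchor, c(0, 0, 50))
  expect_equal(a$direction, c(0, 0, 1), tolerance = 1e-12)
  # exact collinear along (1,1,1)/sqrt(3)
  v <- c(1, 1, 1) / sqrt(3)
  cs <- outer(c(10, 20, 30), v)
  a2 <- estimate_axis(cs)
  expect_equal(abs(sum(a2$direction * v)), 1, tolerance = 1e-9)
  expect_gt(sum(a2$direction * v), 0)      # sign: inner -> outer
  # noisy near-collinear: matches a brute-force ODR direction grid to 0.05 deg
  set.seed(2)
  cs3 <- outer(c(50, 100, 150), v) + matrix(rnorm(9, 0, 0.5), 3, 3)
  a3 <- estimate_axis(cs3)
  odr_cost <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    A <- sweep(cs3, 2, colMeans(cs3))
    sum(rowSums(A^2) - drop(A %*% dir)^2)
  }
  best <- a3$direction; step <- pi / 180
  repeat {
    # local grid over two tangent directions
    t1 <- c(-best[2], best[1], 0); t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(best[2] * t1[3] - best[3] * t1[2],
            best[3] * t1[1] - best[1] * t1[3],
            best[1] * t1[2] - best[2] * t1[1])
    gr <- expand.grid(a = seq(-2, 2) * step, b = seq(-2, 2) * step)
    cand <- t(apply(gr, 1, function(g)
      best + g[1] * t1 + g[2] * t2))
    vals <- apply(cand, 1, odr_cost)
    newbest <- cand[which.min(vals), ]
    newbest <- newbest / sqrt(sum(newbest^2))
    if (odr_cost(newbest) >= odr_cost(best) - 1e-15) {
      if (step < 0.005 * pi / 180) break
      step <- step / 10
    } else best <- newbest
  }
  ang <- acos(min(1, abs(sum(a3$direction * best)))) * 180 / pi
  expect_lt(ang, 0.05)
  expect_error(estimate_axis(rbind(c(1, 1, 1), c(1, 1, 1))), "coincide")
})

test_that("origin estimation solves the three-line least-squares problem", {
  # concurrent orthogonal axes: exact recovery
  g0 <- c(5, -3, 712)
  axes <- list(
    structure(list(anchor = g0 + c(40, 0, 0), direction = c(1, 0, 0)),
              class = "axis_estimate"),
    structure(list(anchor = g0 + c(0, 55, 0), direction = c(0, 1, 0)),
              class = "axis_estimate"),
    structure(list(anchor = g0 + c(0, 0, 70), direction = c(0, 0, 1)),
              class = "axis_estimate"))
  est <- estimate_origin(axes)
  expect_equal(est$origin, g0, tolerance = 1e-9)
  expect_lt(est$residual, 1e-9)

  # skew perturbed axes vs a general numerical minimizer
  set.seed(3)
  axes2 <- lapply(axes, function(a) {
    d <- a$direction + rnorm(3, 0, 0.05)
    structure(list(anchor = a$anchor + rnorm(3, 0, 2),
                   direction = d / sqrt(sum(d^2))),
              class = "axis_estimate")
  })
  est2 <- estimate_origin(axes2)
  cost <- function(g) sum(vapply(axes2, function(a) {
    w <- g - a$anchor
    sum(w^2) - sum(w * a$direction)^2
  }, 0))
  opt <- stats::optim(g0, cost, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 1000))
  expect_lt(sqrt(sum((est2$origin - opt$par)^2)), 1e-6)
  # local optimality: no 1 mm perturbation does better
  set.seed(4)
  for (i in 1:200) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    expect_gte(cost(est2$origin + d), cost(est2$origin) - 1e-12)
  }

  # three coplanar parallel-ish lines are degenerate
  par_axes <- lapply(1:3, function(i)
    structure(list(anchor = c(i * 10, 0, 0), direction = c(0, 0, 1)),
              class = "axis_estimate"))
  expect_error(estimate_origin(par_axes), "degenerate")
})

test_that("build_transform is a proper rotation and handles exact axes", {
  axes <- list(
    x = structure(list(anchor = c(100, 0, 0), direction = c(1, 0, 0)),
                  class = "axis_estimate"),
    y = structure(list(anchor = c(0, 100, 0), direction = c(0, 1, 0)),
                  class = "axis_estimate"),
    z = structure(list(anchor = c(0, 0, 100), direction = c(0, 0, 1)),
                  class = "axis_estimate"))
  org <- structure(list(origin = c(0, 0, 0), residual = 0),
                   class = "origin_estimate")
  tr <- build_transform(org, axes)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-12)
  expect_equal(apply_transform(tr, c(1, 2, 3)), c(1, 2, 3))
  # perturbed axes still give an orthonormal proper rotation
  set.seed(5)
  for (i in 1:20) {
    axes_p <- lapply(axes, function(a) {
      d <- a$direction + rnorm(3, 0, 0.03)
      structure(list(anchor = a$anchor, direction = d / sqrt(sum(d^2))),
                class = "axis_estimate")
    })
    trp <- build_transform(org, axes_p)
    expect_lt(max(abs(crossprod(trp$rotation) - diag(3))), 1e-9)
    expect_equal(det(trp$rotation), 1, tolerance = 1e-9)
  }
  # grossly non-orthogonal axes are rejected
  axes_bad <- axes
  axes_bad$y$direction <- c(0.8, 0.6, 0)
  expect_error(build_transform(org, axes_bad), "orthogonal")
})

test_that("full scaffold calibration recovers a known camera pose", {
  cfg <- default_config()
  scn <- config_calibration_scene(cfg)
  cam <- config_calibration_camera(cfg)
  seeds <- calibration_seeds(cfg, cam)
  pose_errors <- function(noise, n_frames, seed) {
    frames <- render_depth(scn, cam, noise, n_frames, seed = seed)
    calib <- calibrate_scaffold(frames, seeds, cfg$calibration$sphere_radius)
    Rt <- cam$pose$rotation
    rot <- acos(min(1, (sum(diag(crossprod(calib$transform$rotation, Rt)))
                        - 1) / 2)) * 180 / pi
    p <- c(0, 0, 700)
    tr <- sqrt(sum((apply_transform(calib$transform, p) -
                    (drop(Rt %*% p) + cam$pose$translation))^2))
    c(rot = rot, trans = tr)
  }
  # noiseless: exact recovery
  e0 <- pose_errors(0, 20, 900)
  expect_lt(e0["rot"], 1e-3)
  expect_lt(e0["trans"], 1e-2)
  # sigma = 5 mm, 20 frames: within 1 deg / 5 mm
  e5 <- pose_errors(5, 20, 901)
  expect_lt(e5["rot"], 1.0)
  expect_lt(e5["trans"], 5)
  # per-axis sphere counts in 2..4
  frames <- render_depth(scn, cam, 5, 20, seed = 902)
  calib <- calibrate_scaffold(frames, seeds, cfg$calibration$sphere_radius)
  for (a in calib$axes) expect_true(a$n_spheres %in% 2:4)
  # report round trip preserves the transform
  f <- tempfile(fileext = ".yaml")
  write_calibration_report(calib, f)
  tr2 <- read_calibration_report(f)
  expect_equal(tr2$rotation, calib$transform$rotation, tolerance = 1e-6)
  expect_equal(tr2$g, calib$transform$g, tolerance = 1e-6)
})
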