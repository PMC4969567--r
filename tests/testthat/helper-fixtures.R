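# Shared fixtures, built lazily and cached for the session. The end-to-end
# simulation (projections + saturation + depth cloud + corrected stack) is
# by far the most expensive object, so every test that needs it shares one
# instance.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small geometry for cheap unit tests (same physical aperture, 20x coarser)
tiny_geom <- function(n_angles = 9L)
  cone_beam_geometry(n_angles = n_angles, downscale = 20L)

# default study geometry (10x downscaled detector, all 133 views)
study_geom <- function() cone_beam_geometry(downscale = 10L)

# points on a sphere surface (uniform over the full sphere or a cap)
sphere_points <- function(n, center, radius, cap_axis = NULL,
                          cap_cos = -1) {
  z <- stats::runif(n, cap_cos, 1)
  th <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(1 - z^2, 0))
  P <- cbind(r * cos(th), r * sin(th), z) * radius
  if (!is.null(cap_axis)) {
    # rotate +z onto cap_axis
    a <- cap_axis / sqrt(sum(cap_axis^2))
    if (a[3] < -1 + 1e-12) {
      P[, 3] <- -P[, 3]                    # antipodal: flip z
    } else if (abs(a[3]) < 1 - 1e-12) {
      v <- c(-a[2], a[1], 0); v <- v / sqrt(sum(v^2))
      ang <- acos(a[3])
      K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      P <- P %*% t(R)
    }
  }
  sweep(P, 2, center, `+`)
}

# end-to-end clipped-phantom study shared by correction/recon/acceptance
# tests: ground-truth + saturated stacks, depth-derived surface cloud (true
# camera pose), corrected stack.
knee_study <- function() {
  fixture("knee_study", function() {
    cfg <- default_config()
    geom <- study_geom()
    knee <- config_knee_scene(cfg)
    gt <- simulate_projections(knee, geom)
    sat <- apply_saturation(gt, cfg$saturation$p_sat,
                            cfg$saturation$rolloff_width)
    cam <- config_depth_camera(cfg)
    frames <- render_depth(knee, cam, cfg$depth$noise_std,
                           cfg$depth$n_frames, seed = 7001)
    cloud <- object_surface_cloud(frames, cam$pose)
    corr <- correct_stack(sat, cloud)
    list(cfg = cfg, geom = geom, scene = knee, gt = gt, sat = sat,
         cloud = cloud, corr = corr)
  })
}
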