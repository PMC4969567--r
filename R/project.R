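## Analytic forward projection: closed-form ray/primitive chords, vectorized
## over rays. O is an n x 3 matrix of origins, D an n x 3 matrix of unit
## directions; all lengths in mm.

# Entry/exit parameters of rays with one primitive. Returns list(t1, t2);
# misses have t1 = t2 = 0 (zero chord).
.ray_interval <- function(prim, O, D) {
  n <- nrow(O)
  t1 <- numeric(n); t2 <- numeric(n)
  oc <- sweep(O, 2, prim$center)
  if (prim$kind == "sphere") {
    b <- rowSums(oc * D)
    cc <- rowSums(oc * oc) - prim$radius^2
    disc <- b * b - cc
    hit <- disc > 0
    sq <- sqrt(pmax(disc, 0))
    t1[hit] <- (-b - sq)[hit]
    t2[hit] <- (-b + sq)[hit]
  } else {
    a <- prim$axis
    za <- drop(oc %*% a); da <- drop(D %*% a)
    w <- oc - outer(za, a)
    dd <- D - outer(da, a)
    A <- rowSums(dd * dd)
    B <- 2 * rowSums(w * dd)
    C <- rowSums(w * w) - prim$radius^2
    # radial interval
    r1 <- numeric(n); r2 <- numeric(n)
    par <- A < 1e-14                       # ray parallel to the axis
    disc <- B * B - 4 * A * C
    hit <- !par & disc > 0
    sq <- sqrt(pmax(disc, 0))
    r1[hit] <- ((-B - sq) / (2 * A))[hit]
    r2[hit] <- ((-B + sq) / (2 * A))[hit]
    inside_par <- par & C < 0
    r1[inside_par] <- -Inf; r2[inside_par] <- Inf
    # slab interval |za + t da| <= h
    h <- prim$half_length
    s1 <- numeric(n); s2 <- numeric(n)
    perp <- abs(da) < 1e-14
    sa <- (-h - za) / ifelse(perp, 1, da)
    sb <- (+h - za) / ifelse(perp, 1, da)
    s1 <- pmin(sa, sb); s2 <- pmax(sa, sb)
    in_slab <- perp & abs(za) <= h
    s1[perp] <- 0; s2[perp] <- 0
    s1[in_slab] <- -Inf; s2[in_slab] <- Inf
    lo <- pmax(r1, s1); hi <- pmin(r2, s2)
    ok <- (hit | inside_par) & (in_slab | !perp) & hi > lo
    t1[ok] <- lo[ok]; t2[ok] <- hi[ok]
  }
  list(t1 = t1, t2 = t2)
}

# Chord lengths (mm) of unit-direction rays through one primitive.
.ray_chord <- function(prim, O, D) {
  iv <- .ray_interval(prim, O, D)
  pmax(0, iv$t2 - iv$t1)
}

#' Analytic line integral through a scene
#'
#' Sum over primitives of (chord length inside the primitive) x attenuation,
#' using closed-form ray/sphere and ray/finite-cylinder intersections.
#' Overlapping primitives add. Rays are full lines; a miss contributes 0.
#'
#' @param sc a [scene()].
#' @param ray list with `origin` (3-vector) and `direction` (unit 3-vector),
#'   e.g. from [ray_for_pixel()]. `origin`/`direction` may also be n x 3
#'   matrices for many rays at once.
#' @return line integral(s), dimensionless.
#' @export
analytic_line_integral <- function(sc, ray) {
  O <- ray$origin; D <- ray$direction
  if (is.null(dim(O))) O <- matrix(O, 1)
  if (is.null(dim(D))) D <- matrix(D, 1)
  if (nrow(O) == 1 && nrow(D) > 1) O <- O[rep(1, nrow(D)), , drop = FALSE]
  out <- numeric(nrow(D))
  for (prim in sc$primitives)
    if (prim$attenuation > 0)
      out <- out + prim$attenuation * .ray_chord(prim, O, D)
  if (length(out) == 1L) out[[1]] else out
}

#' Simulated cone-beam projection stack
#'
#' Forward-projects a scene over every view of the geometry: each detector
#' pixel holds the analytic line integral of its source-to-pixel ray. The
#' saturation mask starts all-FALSE (see [apply_saturation()]).
#'
#' @param sc a [scene()].
#' @param geom a [cone_beam_geometry()].
#' @return object of class `projection_stack`: list with `data` (array
#'   `det_cols x det_rows x n_angles`), `mask` (same shape, logical) and
#'   `geom`.
#' @export
simulate_projections <- function(sc, geom) {
  nu <- geom$det_cols; nv <- geom$det_rows; na <- geom$n_angles
  data <- array(0, c(nu, nv, na))
  uu <- rep(seq_len(nu) - 1L, times = nv)
  vv <- rep(seq_len(nv) - 1L, each = nu)
  for (k in seq_len(na) - 1L) {
    s <- source_position(geom, k)
    P <- pixel_position(geom, k, uu, vv)
    D <- sweep(P, 2, s)
    D <- D / sqrt(rowSums(D * D))
    O <- matrix(s, nrow(D), 3, byrow = TRUE)
    data[, , k + 1L] <- analytic_line_integral(sc, list(origin = O,
                                                        direction = D))
  }
  projection_stack(data, geom)
}

#' Construct a projection stack
#'
#' @param data `det_cols x det_rows x n_angles` array of line integrals.
#' @param geom a [cone_beam_geometry()].
#' @param mask logical array of the same shape marking saturated pixels.
#' @return a `projection_stack`.
#' @export
projection_stack <- function(data, geom, mask = NULL) {
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L, all(is.finite(data)))
  if (is.null(mask)) mask <- array(FALSE, dim(data))
  stopifnot(all(dim(mask) == dim(data)))
  structure(list(data = data, mask = mask, geom = geom),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("projection stack: %d x %d px, %d views; %.2f%% saturated\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              100 * mean(x$mask)))
  invisible(x)
}

#' Detector saturation model
#'
#' Models overexposure of a flat-panel detector in the line-integral domain:
#' weakly attenuated rays (small line integral `p`) overexpose the detector
#' and their recorded value collapses. Pixels with `p < p_sat` are marked
#' saturated and set to 0. Pixels in the roll-off band
#' `p_sat <= p < p_sat + rolloff_width` are compressed toward `p_sat` by a
#' smooth monotone map (`p_sat + w * x^2`, `x = (p - p_sat)/w`), emulating
#' the vendor's nonlinear preprocessing that drives near-saturated values
#' down; pixels above the band are unchanged.
#'
#' Saturation parameters are recorded on the stack; re-applying the identical
#' model to an already-saturated stack is a no-op (recorded values are no
#' longer line integrals, so re-thresholding them would be meaningless).
#'
#' @param stack a `projection_stack` of clean line integrals.
#' @param p_sat saturation threshold in the line-integral domain, > 0.
#' @param rolloff_width width of the nonlinear roll-off band, >= 0.
#' @return the saturated `projection_stack` (mask set, values reduced).
#' @export
apply_saturation <- function(stack, p_sat, rolloff_width = 0) {
  stopifnot(p_sat > 0, rolloff_width >= 0)
  prev <- attr(stack, "sat_params")
  if (!is.null(prev) && isTRUE(all.equal(prev, c(p_sat, rolloff_width))))
    return(stack)
  p <- stack$data
  mask <- p < p_sat
  out <- p
  out[mask] <- 0
  if (rolloff_width > 0) {
    zone <- !mask & p < p_sat + rolloff_width
    x <- (p[zone] - p_sat) / rolloff_width
    out[zone] <- p_sat + rolloff_width * x^2
  }
  res <- projection_stack(out, stack$geom, mask | stack$mask)
  attr(res, "sat_params") <- c(p_sat, rolloff_width)
  res
}
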