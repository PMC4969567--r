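## Closed (periodic) uniform cubic B-spline curves in the plane.
##
## The curve parameter t lives on [0, 1) with n_ctrl uniform periodic knots;
## evaluation blends 4 consecutive control points with the standard uniform
## cubic basis, so closure is automatic.

# Basis weights and control indices at parameters t (vectorized).
.pbspline_design <- function(t, n_ctrl) {
  u <- (t %% 1) * n_ctrl
  i <- floor(u)
  f <- u - i
  w <- cbind((1 - f)^3,
             3 * f^3 - 6 * f^2 + 4,
             -3 * f^3 + 3 * f^2 + 3 * f + 1,
             f^3) / 6
  A <- matrix(0, length(t), n_ctrl)
  for (k in 0:3) {
    idx <- ((i - 1 + k) %% n_ctrl) + 1
    A[cbind(seq_along(t), idx)] <- A[cbind(seq_along(t), idx)] + w[, k + 1]
  }
  A
}

#' Fit a closed cubic B-spline to planar surface points
#'
#' Least-squares fit of a periodic uniform cubic B-spline to one connected
#' cluster of 2-D surface points, angularly ordered around the cluster
#' centroid. A small second-difference penalty on the control polygon
#' (`smooth`) regularizes sparse or noisy slices.
#'
#' @param points n x 2 matrix of in-plane points (mm), one cluster.
#' @param n_ctrl number of control points (>= 6).
#' @param smooth ridge weight on periodic second differences of the control
#'   polygon (relative to the data term).
#' @return object of class `surface_curve`: `ctrl` (n_ctrl x 2), `n_ctrl`,
#'   `centroid`.
#' @export
fit_closed_spline <- function(points, n_ctrl = 16L, smooth = 1e-2) {
  points <- as.matrix(points)
  if (nrow(points) < 6L) stop("need at least 6 points for a closed spline")
  n_ctrl <- max(6L, as.integer(n_ctrl))
  ctr <- colMeans(points)
  th <- atan2(points[, 2] - ctr[2], points[, 1] - ctr[1])
  o <- order(th)
  t <- (th[o] + pi) / (2 * pi)
  A <- .pbspline_design(t, n_ctrl)
  # periodic second-difference penalty
  D <- matrix(0, n_ctrl, n_ctrl)
  for (j in seq_len(n_ctrl)) {
    D[j, j] <- -2
    D[j, (j %% n_ctrl) + 1] <- 1
    D[j, ((j - 2) %% n_ctrl) + 1] <- 1
  }
  lam <- smooth * nrow(points) / n_ctrl
  H <- crossprod(A) + lam * crossprod(D)
  ctrl <- solve(H, crossprod(A, points[o, , drop = FALSE]))
  structure(list(ctrl = ctrl, n_ctrl = n_ctrl, centroid = ctr),
            class = "surface_curve")
}

#' Evaluate a closed spline curve
#'
#' @param curve a `surface_curve`.
#' @param t parameters in [0, 1) (periodic).
#' @return length(t) x 2 matrix of curve points.
#' @export
eval_spline <- function(curve, t) {
  .pbspline_design(t, curve$n_ctrl) %*% curve$ctrl
}

#' Dense polygonal sampling of a closed curve
#'
#' @param curve a `surface_curve`.
#' @param n number of samples.
#' @return n x 2 matrix of vertices (closing edge implied).
#' @export
spline_polygon <- function(curve, n = 256L) {
  eval_spline(curve, seq(0, 1, length.out = n + 1L)[-(n + 1L)])
}

#' Does a closed curve self-intersect?
#'
#' Brute-force segment-pair test on a dense polygonal sampling; used as a
#' diagnostic flag on degenerate slices.
#'
#' @param curve a `surface_curve`.
#' @param n polygon sampling density.
#' @return logical.
#' @export
spline_self_intersects <- function(curve, n = 128L) {
  P <- spline_polygon(curve, n)
  a <- P; b <- P[c(2:n, 1), ]
  e <- b - a
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]      # skip adjacent (wrap) pairs
    if (!length(js)) next
    w <- sweep(a[js, , drop = FALSE], 2, a[i, ])
    den <- e[i, 1] * e[js, 2] - e[i, 2] * e[js, 1]
    ti <- (w[, 1] * e[js, 2] - w[, 2] * e[js, 1]) / den
    tj <- (w[, 1] * e[i, 2] - w[, 2] * e[i, 1]) / den
    hit <- abs(den) > 1e-12 & ti > 0 & ti < 1 & tj > 0 & tj < 1
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Length of a line inside closed curve(s)
#'
#' Total length of the segments of a 2-D line interior to one or more closed
#' curves (sum over curves; even-odd rule per curve). Crossing parameters
#' are found on a dense polygonal sampling of each curve; consecutive
#' crossing pairs bound the interior intervals. Tangential grazes produce
#' near-coincident crossings whose interval length vanishes, so they do not
#' need special treatment.
#'
#' @param curves a `surface_curve` or list of them.
#' @param line list with `origin` (2-vector) and `direction` (2-vector, need
#'   not be unit).
#' @param n_poly polygon sampling density per curve.
#' @return length in mm (0 for a miss).
#' @export
intersection_length <- function(curves, line, n_poly = 256L) {
  if (inherits(curves, "surface_curve")) curves <- list(curves)
  o <- line$origin
  d <- line$direction / sqrt(sum(line$direction^2))
  total <- 0
  for (cv in curves) {
    P <- spline_polygon(cv, n_poly)
    ts <- .line_polygon_crossings(o, d, P)
    if (length(ts) >= 2L) {
      ts <- sort(ts)
      k <- seq(1L, 2L * (length(ts) %/% 2L), by = 2L)
      total <- total + sum(ts[k + 1L] - ts[k])
    }
  }
  total
}

# Crossing parameters t (along o + t d) of a line with polygon P (rows are
# vertices, implied closing edge). Half-open edge parameter avoids double
# counting at vertices.
.line_polygon_crossings <- function(o, d, P) {
  n <- nrow(P)
  a <- P; b <- P[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  wx <- a[, 1] - o[1];  wy <- a[, 2] - o[2]
  den <- d[1] * ey - d[2] * ex
  s <- (wx * d[2] - wy * d[1]) / den       # edge parameter
  t <- (wx * ey - wy * ex) / den           # line parameter
  keep <- abs(den) > 1e-12 & s >= 0 & s < 1
  t[keep]
}
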