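#' Fit a straight reference axis to a point cloud
#'
#' The cylindrical unwrap of the vessel surface needs a straight reference
#' axis.  It is taken as the first principal direction of the reference-frame
#' node cloud, anchored at the centroid, with a deterministic sign: the
#' direction has a positive component along the global coordinate axis of
#' greatest cloud extent.  All segmentations of one acquisition should be
#' unwrapped with the same axis so that the angular coordinate is comparable.
#'
#' @param points numeric matrix (points x 3), mm.
#' @return list with `origin` (centroid) and `direction` (unit 3-vector).
#' @export
fit_axis <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points to fit an axis")
  ctr <- colMeans(points)
  cen <- sweep(points, 2L, ctr)
  sv <- svd(cen, nu = 0L, nv = 3L)
  if (sv$d[1] < 1e-12) stop("degenerate point cloud: all points coincide")
  if (sv$d[2] < 1e-9 * sv$d[1]) stop("degenerate point cloud: points are collinear")
  dir <- sv$v[, 1]
  ext <- apply(points, 2L, function(v) diff(range(v)))
  k <- which.max(ext)
  if (dir[k] < 0) dir <- -dir
  if (dir[k] == 0 && dir[which.max(abs(dir))] < 0) dir <- -dir
  list(origin = ctr, direction = dir)
}

## deterministic right-handed orthonormal frame (u, v, d) for an axis
axis_frame <- function(axis) {
  d <- axis$direction / sqrt(sum(axis$direction^2))
  k <- which.min(abs(d))
  e <- c(0, 0, 0); e[k] <- 1
  u <- e - sum(e * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v, d = d)
}

#' Cartesian to cylindrical coordinates about a reference axis
#'
#' `x_long` is the signed projection onto the axis direction, `R` the radial
#' distance from the axis and `phi` the angle in `(-pi, pi]` within a fixed
#' right-handed frame constructed deterministically from the axis direction.
#' Points on the axis get `phi = 0` by convention.
#'
#' @param points matrix (points x 3) or a 3-vector, mm.
#' @param axis a [fit_axis()] result.
#' @return data.frame with columns `x_long`, `phi`, `R`.
#' @export
to_cylindrical <- function(points, axis) {
  points <- rbind(as.matrix(points))
  if (ncol(points) != 3L) points <- matrix(points, ncol = 3L)
  fr <- axis_frame(axis)
  rel <- sweep(points, 2L, axis$origin)
  a <- rel %*% fr$u
  b <- rel %*% fr$v
  r <- sqrt(a^2 + b^2)
  phi <- ifelse(r > 0, atan2(b, a), 0)
  data.frame(x_long = as.numeric(rel %*% fr$d), phi = as.numeric(phi),
             R = as.numeric(r))
}

#' Cylindrical back to Cartesian coordinates
#'
#' Inverse of [to_cylindrical()] for the same axis.
#'
#' @param cyl data.frame with `x_long`, `phi`, `R` (or three vectors).
#' @param axis a [fit_axis()] result.
#' @return matrix (points x 3), mm.
#' @export
from_cylindrical <- function(cyl, axis) {
  fr <- axis_frame(axis)
  outer(cyl$x_long, fr$d) + outer(cyl$R * cos(cyl$phi), fr$u) +
    outer(cyl$R * sin(cyl$phi), fr$v) +
    matrix(axis$origin, nrow = length(cyl$x_long), ncol = 3L, byrow = TRUE)
}

## Unwrap the reference frame of a motion grid into the (x_long, phi) plane.
## phi is made continuous across the branch cut: ring 1 is unwrapped into a
## strictly increasing sequence spanning one turn, and every other ring is
## shifted by multiples of 2*pi to lie within pi of its ring-1 column value.
## Returns matrices x (n x m), phi (n x m), R (n x m) plus the 2-pi period
## information needed for queries.
unwrap_reference <- function(grid, axis, frame = 1L) {
  n <- n_heights(grid); m <- n_circ(grid)
  nodes <- frame_nodes(grid, frame)
  cyl <- to_cylindrical(nodes, axis)
  X <- matrix(cyl$x_long, n, m, byrow = TRUE)
  P <- matrix(cyl$phi, n, m, byrow = TRUE)
  R <- matrix(cyl$R, n, m, byrow = TRUE)
  ## ring 1: unwrap into one continuous turn (either winding direction,
  ## since the axis frame's handedness relative to the column order depends
  ## on the fitted axis sign)
  base <- P[1, ]
  for (j in seq_len(m)[-1]) {
    k <- round((base[j - 1] - base[j]) / (2 * pi))
    base[j] <- base[j] + 2 * pi * k
  }
  db <- diff(base)
  if (!(all(db > 0) || all(db < 0)) || abs(base[m] - base[1]) >= 2 * pi)
    stop("circumferential points of ring 1 do not span a single turn")
  for (i in seq_len(n)) {
    k <- round((base - P[i, ]) / (2 * pi))
    P[i, ] <- P[i, ] + 2 * pi * k
  }
  ## fold-over check: mean axial position must be strictly monotone in height
  xm <- rowMeans(X)
  dx <- diff(xm)
  if (!(all(dx > 0) || all(dx < 0))) {
    bad <- which(sign(dx) != sign(dx[which.max(abs(dx))]))[1]
    stop(sprintf("axial fold-over between heights %d and %d", bad, bad + 1L))
  }
  list(x = X, phi = P, R = R, nodes = nodes, phi0 = base[1],
       wrap_shift = 2 * pi * sign(base[m] - base[1]))
}
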