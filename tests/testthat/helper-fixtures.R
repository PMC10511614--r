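# Fixture builders shared across the test files.

## structured tube grid: radius may be a scalar, a function of axial
## station, or given per frame via `radius_by_frame`; axial scaling per frame
## via `axial_by_frame`.
tube_grid <- function(n = 6, m = 36, radius = 10, len = 40, frames = 2,
                      radius_by_frame = NULL, axial_by_frame = NULL,
                      center = c(0, 0, 0), axis_dir = c(0, 0, 1)) {
  xs <- seq(0, len, length.out = n)
  phis <- -pi + (seq_len(m) - 0.5) * 2 * pi / m
  gg <- expand.grid(phi = phis, x = xs)
  pos <- array(NA_real_, c(frames, n, m, 3))
  for (t in seq_len(frames)) {
    r <- if (!is.null(radius_by_frame)) radius_by_frame[t]
         else if (is.function(radius)) radius(gg$x) else radius
    ax <- if (!is.null(axial_by_frame)) axial_by_frame[t] else 1
    ## build along z then rotate so that the tube axis is axis_dir
    pts <- cbind(r * cos(gg$phi), r * sin(gg$phi), ax * gg$x)
    if (!all(axis_dir == c(0, 0, 1))) {
      R <- rotation_to(c(0, 0, 1), axis_dir)
      pts <- pts %*% t(R)
    }
    pts <- sweep(pts, 2, center, "+")
    for (k in 1:3) pos[t, , , k] <- matrix(pts[, k], n, m, byrow = TRUE)
  }
  motion_grid(pos)
}

## rotation matrix taking unit vector a to unit vector b
rotation_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) return(diag(c(-1, -1, 1)))
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

## arbitrary small rotation matrix from three angles (independent of the
## package's Rx Ry Rz convention; used for equivariance checks)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}

## planar reference element embedded in 3D via an orthonormal pair (u1, u2);
## X2d is 4 x 2 (longitudinal, circumferential local coordinates)
embed_element <- function(X2d, origin = c(0, 0, 0), u1 = c(1, 0, 0),
                          u2 = c(0, 1, 0)) {
  t(apply(X2d, 1L, function(p) origin + p[1] * u1 + p[2] * u2))
}

## unit square element (longitudinal edge along u1)
unit_element <- function(a = 1, b = 1) {
  ## node order (i,j),(i,j+1),(i+1,j+1),(i+1,j): circumferential = dim 2
  rbind(c(0, 0), c(0, b), c(a, b), c(a, 0))
}

## independent eigendecomposition oracle for the Biot strain of a 2x2
## deformation gradient
biot_oracle <- function(Fm) {
  C <- t(Fm) %*% Fm
  eg <- eigen(C, symmetric = TRUE)
  U <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
  U - diag(2)
}

## brute-force nearest neighbour with lowest-index tie rule
nn_brute <- function(static, query) {
  idx <- integer(nrow(query)); d <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    dd <- sqrt(colSums((t(static) - query[i, ])^2))
    j <- which(dd == min(dd))[1]
    idx[i] <- j; d[i] <- dd[j]
  }
  list(index = idx, distance = d)
}

## exact left-tail Mann-Whitney p by enumeration of all group assignments
mw_left_exact <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  rk <- rank(all)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(all), n1)
  us <- apply(combs, 2L, function(id) sum(rk[id]) - n1 * (n1 + 1) / 2)
  mean(us <= u_obs)
}
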