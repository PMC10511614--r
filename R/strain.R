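#' Local element coordinate frame
#'
#' Builds the in-plane orthonormal frame of a quadrilateral wall element:
#' the 2-axis (`e2`, circumferential) is the normalised mean of the two
#' circumferential edge vectors, the 1-axis (`e1`, longitudinal) is the mean
#' of the two longitudinal edge vectors orthogonalised against `e2`
#' (Gram-Schmidt).  The origin is the node mean (centroid).  Frames are
#' recomputed for every deformed configuration, which removes solid-body
#' motion from the strain measure.
#'
#' @param nodes 4 x 3 matrix of the element's node positions, in the stored
#'   node order (see [build_quad_mesh()]).
#' @return list with unit vectors `e1`, `e2` and `origin`.
#' @export
local_frame <- function(nodes) {
  f <- local_frames_batch(array(nodes, c(1L, 4L, 3L)))
  list(e1 = f$e1[1, ], e2 = f$e2[1, ], origin = f$origin[1, ])
}

## batched frames: els is (nel x 4 x 3) -> e1, e2, origin each (nel x 3)
local_frames_batch <- function(els) {
  p1 <- els[, 1, , drop = TRUE]; p2 <- els[, 2, , drop = TRUE]
  p3 <- els[, 3, , drop = TRUE]; p4 <- els[, 4, , drop = TRUE]
  if (is.null(dim(p1))) {
    p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  }
  circ <- ((p2 - p1) + (p3 - p4)) / 2
  long <- ((p4 - p1) + (p3 - p2)) / 2
  n2 <- sqrt(rowSums(circ^2))
  if (any(n2 < 1e-12)) stop("degenerate element: zero circumferential edge")
  e2 <- circ / n2
  proj <- rowSums(long * e2)
  l <- long - proj * e2
  n1 <- sqrt(rowSums(l^2))
  if (any(n1 < 1e-12)) stop("degenerate element: zero longitudinal extent")
  e1 <- l / n1
  list(e1 = e1, e2 = e2, origin = (p1 + p2 + p3 + p4) / 4)
}

## project element nodes into their local in-plane 2D coordinates:
## coordinate 1 along e1 (longitudinal), 2 along e2 (circumferential).
## els (nel x 4 x 3) -> list(X1, X2) each (nel x 4)
project_inplane <- function(els, fr) {
  X1 <- matrix(0, dim(els)[1], 4L)
  X2 <- X1
  for (a in 1:4) {
    rel <- els[, a, , drop = TRUE]
    if (is.null(dim(rel))) rel <- rbind(rel)
    rel <- rel - fr$origin
    X1[, a] <- rowSums(rel * fr$e1)
    X2[, a] <- rowSums(rel * fr$e2)
  }
  list(X1 = X1, X2 = X2)
}

## 2x2 in-plane deformation gradient at the element centroid (r = s = 0)
## from reference and current projected coordinates; batched.
## Shape-function derivatives at the centroid reduce to +-1/4 patterns.
defgrad_centroid <- function(ref, cur) {
  gcol <- function(X, w) (w[1] * X[, 1] + w[2] * X[, 2] + w[3] * X[, 3] +
                            w[4] * X[, 4]) / 4
  wr <- c(-1, 1, 1, -1)   # d/dr
  ws <- c(-1, -1, 1, 1)   # d/ds
  ## Jacobian columns (d x / d r, d x / d s) for reference and current
  a11 <- gcol(ref$X1, wr); a12 <- gcol(ref$X1, ws)
  a21 <- gcol(ref$X2, wr); a22 <- gcol(ref$X2, ws)
  b11 <- gcol(cur$X1, wr); b12 <- gcol(cur$X1, ws)
  b21 <- gcol(cur$X2, wr); b22 <- gcol(cur$X2, ws)
  det <- a11 * a22 - a12 * a21
  ## F = J_cur %*% solve(J_ref)
  f11 <- (b11 * a22 - b12 * a21) / det
  f12 <- (-b11 * a12 + b12 * a11) / det
  f21 <- (b21 * a22 - b22 * a21) / det
  f22 <- (-b21 * a12 + b22 * a11) / det
  list(f11 = f11, f12 = f12, f21 = f21, f22 = f22,
       detF = f11 * f22 - f12 * f21, detJref = det)
}

## closed-form principal square root of a symmetric positive-definite 2x2
## matrix C: U = (C + sqrt(det C) I) / sqrt(tr C + 2 sqrt(det C)); falls back
## to an eigendecomposition when the denominator is tiny.
sqrtm2 <- function(c11, c12, c22) {
  dt <- c11 * c22 - c12^2
  sq <- sqrt(pmax(dt, 0))
  den <- sqrt(c11 + c22 + 2 * sq)
  u11 <- (c11 + sq) / den
  u12 <- c12 / den
  u22 <- (c22 + sq) / den
  bad <- which(!is.finite(den) | den < 1e-12)
  for (b in bad) {
    eg <- eigen(matrix(c(c11[b], c12[b], c12[b], c22[b]), 2L), symmetric = TRUE)
    U <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
    u11[b] <- U[1, 1]; u12[b] <- U[1, 2]; u22[b] <- U[2, 2]
  }
  list(u11 = u11, u12 = u12, u22 = u22)
}

#' In-plane Biot strain of one element
#'
#' Computes the in-plane Biot strain tensor `eps = U - I` of a quadrilateral
#' element between a reference and a current configuration, where `U` is the
#' right stretch tensor of the in-plane deformation gradient evaluated at the
#' element centroid (`r = s = 0`).  Both configurations are projected into
#' their own local frames (see [local_frame()]), so the measure is free of
#' rigid-body motion; the components are reported in the reference local
#' frame with axis 1 longitudinal and axis 2 circumferential.
#'
#' @param ref_nodes,cur_nodes 4 x 3 matrices of node positions, mm.
#' @return named vector `c(eps11, eps22, eps12)` (dimensionless).
#' @export
biot_strain <- function(ref_nodes, cur_nodes) {
  e <- biot_strain_batch(array(ref_nodes, c(1L, 4L, 3L)),
                         array(cur_nodes, c(1L, 4L, 3L)))
  c(eps11 = e$eps11[1], eps22 = e$eps22[1], eps12 = e$eps12[1])
}

## batched Biot strain: refs/curs (nel x 4 x 3)
biot_strain_batch <- function(refs, curs) {
  fr0 <- local_frames_batch(refs)
  frt <- local_frames_batch(curs)
  X <- project_inplane(refs, fr0)
  x <- project_inplane(curs, frt)
  Fg <- defgrad_centroid(X, x)
  if (any(Fg$detF <= 0)) {
    b <- which(Fg$detF <= 0)[1]
    stop(sprintf("element inversion (det F = %.3g <= 0) in element %d",
                 Fg$detF[b], b))
  }
  c11 <- Fg$f11^2 + Fg$f21^2
  c12 <- Fg$f11 * Fg$f12 + Fg$f21 * Fg$f22
  c22 <- Fg$f12^2 + Fg$f22^2
  U <- sqrtm2(c11, c12, c22)
  list(eps11 = U$u11 - 1, eps22 = U$u22 - 1, eps12 = U$u12)
}

#' Biot strain series of a wall-motion grid
#'
#' Applies [biot_strain()] to every element of the meshed grid for every
#' frame against the end-diastolic reference (frame 1).  Elements with
#' extreme aspect ratio or vanishing area in the reference configuration are
#' flagged (`degenerate`); they are kept in the table but should be excluded
#' from distribution indices.
#'
#' @param grid a [motion_grid()] (a segmentation or an averaged model).
#' @param mesh optional [build_quad_mesh()]; built from `grid` when missing.
#' @param max_aspect,min_area degeneracy thresholds (ratio of in-plane edge
#'   lengths, and reference element area in mm^2).
#' @return object of class `strain_field`: arrays `eps11`, `eps22`, `eps12`
#'   of dimension (frames x elements), the mesh, and a logical `degenerate`
#'   flag per element.
#' @export
strain_series <- function(grid, mesh = NULL, max_aspect = 100, min_area = 1e-6) {
  if (is.null(mesh)) mesh <- build_quad_mesh(grid)
  tt <- n_frames(grid)
  nel <- nrow(mesh$elements)
  ref_nodes <- frame_nodes(grid, 1L)
  refs <- array(ref_nodes[mesh$elements, ], c(nel, 4L, 3L))
  eps11 <- matrix(0, tt, nel)
  eps22 <- matrix(0, tt, nel)
  eps12 <- matrix(0, tt, nel)
  for (t in seq_len(tt)[-1]) {
    nodes <- frame_nodes(grid, t)
    curs <- array(nodes[mesh$elements, ], c(nel, 4L, 3L))
    e <- tryCatch(biot_strain_batch(refs, curs), error = function(err)
      stop("frame ", t, ": ", conditionMessage(err), call. = FALSE))
    eps11[t, ] <- e$eps11
    eps22[t, ] <- e$eps22
    eps12[t, ] <- e$eps12
  }
  ## degeneracy flags from the reference configuration
  fr0 <- local_frames_batch(refs)
  X <- project_inplane(refs, fr0)
  len1 <- (abs(X$X1[, 4] - X$X1[, 1]) + abs(X$X1[, 3] - X$X1[, 2])) / 2
  len2 <- (abs(X$X2[, 2] - X$X2[, 1]) + abs(X$X2[, 3] - X$X2[, 4])) / 2
  aspect <- pmax(len1, len2) / pmax(pmin(len1, len2), 1e-300)
  area <- abs(defgrad_centroid(X, X)$detJref) * 4
  degenerate <- aspect > max_aspect | area < min_area
  if (any(degenerate))
    message(sum(degenerate), " degenerate element(s) flagged")
  structure(list(eps11 = eps11, eps22 = eps22, eps12 = eps12, mesh = mesh,
                 degenerate = degenerate),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d frames x %d elements (%d degenerate)\n",
              nrow(x$eps11), ncol(x$eps11), sum(x$degenerate)))
  invisible(x)
}

#' Peak-to-peak strain amplitudes
#'
#' Reduces a strain series to one value per element and component: the
#' difference between the largest and smallest strain over the cardiac
#' cycle (the extremes may occur at different frames; the reference frame's
#' zero strain is included).
#'
#' @param field a [strain_series()] result.
#' @return data.frame with columns `element`, `amp11`, `amp22` (dimensionless
#'   fractions) and `degenerate`.
#' @export
strain_amplitudes <- function(field) {
  if (nrow(field$eps11) < 2L) stop("need at least 2 frames for amplitudes")
  rng <- function(M) apply(M, 2L, max) - apply(M, 2L, min)
  data.frame(element = seq_len(ncol(field$eps11)),
             amp11 = rng(field$eps11), amp22 = rng(field$eps22),
             degenerate = field$degenerate)
}
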