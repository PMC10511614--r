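#' Bilinear quadrilateral shape functions
#'
#' Standard isoparametric shape functions of the 4-node quadrilateral,
#' `N_a(r, s) = (1 + r r_a)(1 + s s_a) / 4` with local node coordinates
#' `(r_a, s_a) = (-1,-1), (1,-1), (1,1), (-1,1)` matching the stored element
#' node order.  They sum to 1 for any `(r, s)` and reduce to a Kronecker
#' delta at the nodes.
#'
#' @param r,s local coordinates (vectors of equal length are accepted).
#' @return numeric matrix (length(r) x 4) of weights.
#' @export
shape_functions <- function(r, s) {
  cbind((1 - r) * (1 - s), (1 + r) * (1 - s),
        (1 + r) * (1 + s), (1 - r) * (1 + s)) / 4
}

## derivatives dN/dr and dN/ds, each length(r) x 4
shape_function_derivs <- function(r, s) {
  list(dr = cbind(-(1 - s), (1 - s), (1 + s), -(1 + s)) / 4,
       ds = cbind(-(1 - r), -(1 + r), (1 + r), (1 - r)) / 4)
}

## forward bilinear map for a batch: xn, yn are (q x 4) node coordinates,
## r, s length-q vectors -> list(x, y)
bilinear_map <- function(xn, yn, r, s) {
  N <- shape_functions(r, s)
  list(x = rowSums(N * xn), y = rowSums(N * yn))
}

## Batch inverse bilinear map by damped Newton iteration from (0, 0).
## xn, yn: (q x 4) element node coordinates; px, py: query points.
## Returns list(r, s, converged).  Steps are clamped to +-1 per iteration,
## which keeps the iteration inside the basin for convex quads.
inverse_bilinear <- function(xn, yn, px, py, tol = 1e-10, maxit = 50L) {
  q <- length(px)
  r <- numeric(q); s <- numeric(q)
  act <- seq_len(q)
  for (it in seq_len(maxit)) {
    xa <- xn[act, , drop = FALSE]; ya <- yn[act, , drop = FALSE]
    f <- bilinear_map(xa, ya, r[act], s[act])
    fx <- f$x - px[act]; fy <- f$y - py[act]
    res2 <- fx^2 + fy^2
    live <- res2 > tol^2
    if (!any(live)) { act <- integer(0); break }
    if (!all(live)) {
      keep <- which(live)
      act <- act[keep]
      xa <- xa[keep, , drop = FALSE]; ya <- ya[keep, , drop = FALSE]
      fx <- fx[keep]; fy <- fy[keep]
    }
    d <- shape_function_derivs(r[act], s[act])
    j11 <- rowSums(d$dr * xa); j12 <- rowSums(d$ds * xa)
    j21 <- rowSums(d$dr * ya); j22 <- rowSums(d$ds * ya)
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-300] <- NA_real_
    dr <- (j22 * fx - j12 * fy) / det
    ds <- (-j21 * fx + j11 * fy) / det
    dr <- pmax(pmin(dr, 1), -1)   # damping: clamp steps to the cell scale
    ds <- pmax(pmin(ds, 1), -1)
    dr[!is.finite(dr)] <- 0
    ds[!is.finite(ds)] <- 0
    r[act] <- r[act] - dr
    s[act] <- s[act] - ds
  }
  f <- bilinear_map(xn, yn, r, s)
  conv <- (f$x - px)^2 + (f$y - py)^2 <= tol^2
  list(r = r, s = s, converged = conv)
}

## Exhaustive fallback for queries where Newton failed: refine on a shrinking
## (r, s) lattice.  Rarely used; handles strongly warped elements.
inverse_bilinear_subdivide <- function(xn, yn, px, py, tol = 1e-10) {
  r0 <- 0; s0 <- 0; h <- 1
  for (level in 1:40) {
    rr <- r0 + h * seq(-1, 1, length.out = 9L)
    ss <- s0 + h * seq(-1, 1, length.out = 9L)
    gg <- expand.grid(r = rr, s = ss)
    gg$r <- pmax(pmin(gg$r, 1.5), -1.5)
    gg$s <- pmax(pmin(gg$s, 1.5), -1.5)
    f <- bilinear_map(matrix(xn, nrow(gg), 4, byrow = TRUE),
                      matrix(yn, nrow(gg), 4, byrow = TRUE), gg$r, gg$s)
    d2 <- (f$x - px)^2 + (f$y - py)^2
    b <- which.min(d2)
    r0 <- gg$r[b]; s0 <- gg$s[b]
    if (sqrt(d2[b]) <= tol) return(list(r = r0, s = s0, converged = TRUE))
    h <- h / 3
  }
  list(r = r0, s = s0, converged = FALSE)
}

#' Locate points inside an unwrapped quadrilateral mesh
#'
#' Finds, for each query point in the unwrapped `(x_long, phi)` plane, the
#' host element of a structured surface mesh and the local isoparametric
#' coordinates `(r, s)` such that the bilinear map of the host element
#' reproduces the query.  Elements spanning the circumferential branch cut
#' are handled by evaluating queries shifted by multiples of 2*pi.
#'
#' @param queries matrix/data.frame with columns `x_long` and `phi`.
#' @param unwrapped an unwrapped reference surface as produced internally by
#'   [interpolate_reference_surface()] (fields `x`, `phi` as n x m matrices).
#' @param mesh the [build_quad_mesh()] of the same grid.
#' @param tol acceptance tolerance on |r|, |s| beyond 1.
#' @return data.frame with columns `element`, `r`, `s`, `shift` (the 2*pi
#'   multiple applied to the query angle).
#' @export
locate_in_element <- function(queries, unwrapped, mesh, tol = 1e-6) {
  queries <- as.data.frame(queries)
  qx <- queries$x_long; qphi <- queries$phi
  nq <- length(qx)
  ## element corner coordinates in the unwrapped plane (element order as in mesh)
  Xn <- unwrap_corner_coords(unwrapped, mesh)
  ex <- Xn$ex; ey <- Xn$ey                      # (nel x 4)
  cx <- rowMeans(ex); cy <- rowMeans(ey)
  bx0 <- apply(ex, 1L, min); bx1 <- apply(ex, 1L, max)
  by0 <- apply(ey, 1L, min); by1 <- apply(ey, 1L, max)
  ## per-dimension slack: the plane mixes mm (axial) and radians (angular)
  mx <- 1e-9 + 0.25 * stats::median(bx1 - bx0)
  my <- 1e-9 + 0.25 * stats::median(by1 - by0)
  out_el <- integer(nq); out_r <- numeric(nq); out_s <- numeric(nq)
  out_shift <- numeric(nq)
  ## candidate host search per query over the 2*pi images of the angle
  ## (4*pi images are reachable when the branch starts near +pi and tilt or
  ## noise drifts a column across the cut)
  for (shift in c(0, 2 * pi, -2 * pi, 4 * pi, -4 * pi)) {
    todo <- which(out_el == 0L)
    if (!length(todo)) break
    py <- qphi[todo] + shift
    px <- qx[todo]
    inside <- which(px >= min(bx0) - mx & px <= max(bx1) + mx &
                    py >= min(by0) - my & py <= max(by1) + my)
    if (!length(inside)) next
    idx <- todo[inside]
    res <- locate_candidates(px[inside], py[inside], ex, ey, cx, cy,
                             bx0, bx1, by0, by1, mx, my, tol)
    hit <- res$element > 0L
    out_el[idx[hit]] <- res$element[hit]
    out_r[idx[hit]] <- res$r[hit]
    out_s[idx[hit]] <- res$s[hit]
    out_shift[idx[hit]] <- shift
  }
  if (any(out_el == 0L)) {
    bad <- which(out_el == 0L)[1]
    stop(sprintf("query point (x=%.4g, phi=%.4g) lies in no element",
                 qx[bad], qphi[bad]))
  }
  data.frame(element = out_el, r = out_r, s = out_s, shift = out_shift)
}

## corner coordinates of every element in the unwrapped plane
unwrap_corner_coords <- function(unwrapped, mesh) {
  xv <- as.numeric(t(unwrapped$x))    # node id order: (i-1)*m + j
  pv <- as.numeric(t(unwrapped$phi))
  e <- mesh$elements
  ex <- matrix(xv[e], ncol = 4L)
  ey <- matrix(pv[e], ncol = 4L)
  ## wrap elements (j = m): their j+1 corners sit one turn away; shift them
  ## onto the continuous branch (sign follows the ring winding direction)
  jwrap <- mesh$el_ij[, "j"] == mesh$m
  if (any(jwrap)) {
    sh <- unwrapped$wrap_shift %||% (2 * pi)
    ey[jwrap, 2] <- ey[jwrap, 2] + sh
    ey[jwrap, 3] <- ey[jwrap, 3] + sh
  }
  list(ex = ex, ey = ey)
}

## even-odd ray-cast containment test of points against one quad
point_in_quad <- function(px, py, qx, qy) {
  inside <- rep(FALSE, length(px))
  j <- 4L
  for (i in 1:4) {
    yi <- qy[i]; yj <- qy[j]
    cross <- (yi > py) != (yj > py)
    if (any(cross)) {
      xin <- (qx[j] - qx[i]) * (py - yi) / (yj - yi) + qx[i]
      inside <- xor(inside, cross & px < xin)
    }
    j <- i
  }
  inside
}

## Host-element assignment in three passes: (1) batch Newton on the element
## whose quad contains the query (exact ray-cast containment), (2) batch
## Newton on the nearest-centroid bbox candidate for boundary stragglers,
## (3) per-query sweep over all bbox candidates with a subdivision fallback.
locate_candidates <- function(px, py, ex, ey, cx, cy, bx0, bx1, by0, by1,
                              mx, my, tol) {
  nq <- length(px)
  el <- integer(nq); rr <- numeric(nq); ss <- numeric(nq)
  try_batch <- function(cand, idx) {
    inv <- inverse_bilinear(ex[cand, , drop = FALSE],
                            ey[cand, , drop = FALSE], px[idx], py[idx])
    good <- inv$converged & abs(inv$r) <= 1 + tol & abs(inv$s) <= 1 + tol
    el[idx[good]] <<- cand[good]
    rr[idx[good]] <<- inv$r[good]
    ss[idx[good]] <<- inv$s[good]
  }
  ## pass 1: exact containment (loop over elements, vectorised over queries;
  ## the first containing element in id order wins, which is deterministic)
  host <- integer(nq)
  open_n <- nq
  for (e in seq_len(nrow(ex))) {
    if (!open_n) break
    open <- which(host == 0L)
    io <- open[px[open] >= bx0[e] & px[open] <= bx1[e] &
               py[open] >= by0[e] & py[open] <= by1[e]]
    if (!length(io)) next
    inq <- point_in_quad(px[io], py[io], ex[e, ], ey[e, ])
    if (any(inq)) {
      host[io[inq]] <- e
      open_n <- open_n - sum(inq)
    }
  }
  hit <- which(host > 0L)
  if (length(hit)) try_batch(host[hit], hit)
  ## pass 2: nearest centroid (scaled metric) for points on element borders
  rest <- which(el == 0L)
  if (length(rest)) {
    d2 <- outer(px[rest], cx, "-")^2 / mx^2 + outer(py[rest], cy, "-")^2 / my^2
    cand1 <- max.col(-d2, ties.method = "first")
    near <- px[rest] >= bx0[cand1] - mx & px[rest] <= bx1[cand1] + mx &
      py[rest] >= by0[cand1] - my & py[rest] <= by1[cand1] + my
    if (any(near)) try_batch(cand1[near], rest[near])
  }
  ## pass 3: exhaustive per-query sweep
  for (q in which(el == 0L)) {
    cands <- which(px[q] >= bx0 - mx & px[q] <= bx1 + mx &
                   py[q] >= by0 - my & py[q] <= by1 + my)
    cands <- cands[order((cx[cands] - px[q])^2 / mx^2 +
                           (cy[cands] - py[q])^2 / my^2)]
    for (ce in cands) {
      iv <- inverse_bilinear(ex[ce, , drop = FALSE], ey[ce, , drop = FALSE],
                             px[q], py[q])
      if (!iv$converged)
        iv <- inverse_bilinear_subdivide(ex[ce, ], ey[ce, ], px[q], py[q])
      if (iv$converged && abs(iv$r) <= 1 + tol && abs(iv$s) <= 1 + tol) {
        el[q] <- ce; rr[q] <- iv$r; ss[q] <- iv$s
        break
      }
    }
  }
  list(element = el, r = rr, s = ss)
}
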