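#' Quadrilateral surface mesh of a motion grid
#'
#' Connects the structured grid into (n-1) x m quadrilateral elements that
#' are closed in the circumferential direction (column `m` connects back to
#' column 1).  Element (i, j) has the node order
#' `(i,j), (i,j+1), (i+1,j+1), (i+1,j)` (counter-clockwise seen from outside
#' the vessel), which fixes the isoparametric (r, s) convention used for
#' shape-function interpolation: r runs circumferentially, s longitudinally.
#'
#' @param grid a [motion_grid()] (or anything with `n_heights`/`n_circ`).
#' @return an object of class `quad_mesh` with fields `n`, `m`, `elements`
#'   (element x 4 matrix of 1-based node ids, node id = `(i-1)*m + j`) and
#'   `el_ij` (element x 2 matrix of 1-based (i, j) element indices).
#' @export
build_quad_mesh <- function(grid) {
  n <- n_heights(grid)
  m <- n_circ(grid)
  if (n < 2L) stop("need at least 2 heights to build elements")
  ij <- expand.grid(j = seq_len(m), i = seq_len(n - 1L))
  i <- ij$i; j <- ij$j
  jp <- j %% m + 1L
  nid <- function(i, j) (i - 1L) * m + j
  elements <- cbind(nid(i, j), nid(i, jp), nid(i + 1L, jp), nid(i + 1L, j))
  structure(list(n = n, m = m, elements = elements, el_ij = cbind(i = i, j = j)),
            class = "quad_mesh")
}

#' @export
print.quad_mesh <- function(x, ...) {
  cat(sprintf("<quad_mesh> %d elements (%d x %d nodes, circumferentially closed)\n",
              nrow(x$elements), x$n, x$m))
  invisible(x)
}

#' Total surface area of a meshed frame
#'
#' Sums element areas (each quad split into two triangles).  Used mainly as a
#' sanity check: for a meshed cylinder the sum approaches 2*pi*rho*L as the
#' grid is refined.
#'
#' @param mesh a [build_quad_mesh()] result.
#' @param nodes node coordinate matrix of one frame (rows follow node ids).
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh, nodes) {
  e <- mesh$elements
  p1 <- nodes[e[, 1], , drop = FALSE]; p2 <- nodes[e[, 2], , drop = FALSE]
  p3 <- nodes[e[, 3], , drop = FALSE]; p4 <- nodes[e[, 4], , drop = FALSE]
  tri <- function(a, b, c) {
    u <- b - a; v <- c - a
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    0.5 * sqrt(rowSums(cr^2))
  }
  sum(tri(p1, p2, p3) + tri(p1, p3, p4))
}
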