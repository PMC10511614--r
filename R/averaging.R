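#' Interpolant of a segmentation's reference surface
#'
#' Unwraps the reference frame (frame 1, end-diastole) of a segmentation into
#' cylindrical coordinates about `axis` and returns a bilinear interpolant on
#' the structured `(x_long, phi)` node grid, periodic in `phi`.  Evaluating
#' at a node's own `(x_long, phi)` reproduces that node exactly; queries
#' outside the axial range of the grid are an error.
#'
#' @param grid a [motion_grid()].
#' @param axis a [fit_axis()] result (shared by all segmentations of one
#'   acquisition).
#' @return function `(x_long, phi)` returning a data.frame with columns `R`
#'   and `x`, `y`, `z` (interpolated radial distance and Cartesian position).
#'   The returned closure also carries the unwrap and mesh as attributes for
#'   reuse by [make_homogeneous_grid()].
#' @export
interpolate_reference_surface <- function(grid, axis) {
  uw <- unwrap_reference(grid, axis)
  mesh <- build_quad_mesh(grid)
  nodes <- uw$nodes
  Rv <- as.numeric(t(uw$R))
  f <- function(x_long, phi) {
    loc <- locate_in_element(data.frame(x_long = x_long, phi = phi), uw, mesh)
    N <- shape_functions(loc$r, loc$s)
    e <- mesh$elements[loc$element, , drop = FALSE]
    xyz <- sapply(1:3, function(k) rowSums(N * matrix(nodes[e, k], ncol = 4L)))
    xyz <- matrix(xyz, ncol = 3L)
    data.frame(R = rowSums(N * matrix(Rv[e], ncol = 4L)),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  attr(f, "unwrapped") <- uw
  attr(f, "mesh") <- mesh
  attr(f, "grid") <- grid
  f
}

#' Lay out a homogeneous re-mesh over several segmentations
#'
#' Builds the common homogeneous grid used for averaging: `m_H` equally
#' spaced angular targets over one turn and `n_H` equally spaced axial
#' targets spanning the axial interval shared by all segmentations, inset by
#' half a mean axial element length so every target is strictly interior.
#' For every segmentation each target is anchored inside its host element
#' (host id plus local `(r, s)`), and the reference position of the target on
#' that segmentation's surface is recorded.
#'
#' @param segmentations list of [motion_grid()] objects of one acquisition
#'   (same frame count; node counts may differ).
#' @param axis a [fit_axis()] result, shared across segmentations.
#' @param n_H,m_H homogeneous grid dimensions.  Defaults: the smallest
#'   height count over the segmentations, and 36 angular positions, so the
#'   re-mesh never exceeds the measured resolution.
#' @return object of class `homogeneous_grid`: targets (`x_long`, `phi`),
#'   grid dims, and per segmentation the anchors and reference positions.
#' @export
make_homogeneous_grid <- function(segmentations, axis, n_H = NULL, m_H = 36L) {
  stopifnot(length(segmentations) >= 1L)
  tt <- vapply(segmentations, n_frames, integer(1))
  if (length(unique(tt)) != 1L)
    stop("segmentations of one acquisition must share the frame count")
  if (is.null(n_H)) n_H <- min(vapply(segmentations, n_heights, integer(1)))
  surfs <- lapply(segmentations, interpolate_reference_surface, axis = axis)
  uws <- lapply(surfs, attr, "unwrapped")
  ## conservative axial interval of one surface: its boundary rings are not
  ## exactly axis-normal (tilt, noise), so take the worst angular position
  rng <- vapply(uws, function(u) {
    n <- nrow(u$x)
    ends <- if (mean(u$x[n, ]) > mean(u$x[1, ])) c(1L, n) else c(n, 1L)
    c(max(u$x[ends[1], ]), min(u$x[ends[2], ]))
  }, numeric(2))
  lo <- max(rng[1, ])
  hi <- min(rng[2, ])
  if (hi <= lo) stop("segmentations have no common axial interval")
  dxm <- mean(vapply(uws, function(u) mean(diff(rowMeans(u$x))), numeric(1)))
  lo2 <- lo + abs(dxm) / 2
  hi2 <- hi - abs(dxm) / 2
  if (hi2 <= lo2) stop("axial overlap shorter than one element length")
  xt <- seq(lo2, hi2, length.out = n_H)
  pt <- -pi + (seq_len(m_H) - 0.5) * 2 * pi / m_H
  tg <- expand.grid(phi = pt, x_long = xt)[, c("x_long", "phi")]
  per_seg <- lapply(seq_along(segmentations), function(k) {
    uw <- uws[[k]]
    mesh <- attr(surfs[[k]], "mesh")
    anchor <- locate_in_element(tg, uw, mesh)
    ## reference position from the anchor's own shape-function combination
    ## (identical to evaluating the reference interpolant at the target)
    N <- shape_functions(anchor$r, anchor$s)
    e <- mesh$elements[anchor$element, , drop = FALSE]
    ref <- sapply(1:3, function(cc)
      rowSums(N * matrix(uw$nodes[e, cc], ncol = 4L)))
    list(anchor = anchor, ref = matrix(ref, ncol = 3L), mesh = mesh)
  })
  structure(list(targets = tg, n_H = n_H, m_H = m_H, axis = axis,
                 per_seg = per_seg,
                 segmentation_ids = vapply(segmentations, function(g)
                   g$segmentation_id, character(1))),
            class = "homogeneous_grid")
}

#' @export
print.homogeneous_grid <- function(x, ...) {
  cat(sprintf("<homogeneous_grid> %d x %d targets, %d segmentations\n",
              x$n_H, x$m_H, length(x$per_seg)))
  invisible(x)
}

#' Track anchored homogeneous points through the cardiac cycle
#'
#' Each homogeneous point keeps its local `(r, s)` position inside its host
#' element; its trajectory is the shape-function combination of the host
#' element's measured node trajectories, `H^t = sum_a N_a(r, s) x^t_a`.
#'
#' @param anchor data.frame from [locate_in_element()] (one row per point).
#' @param grid the [motion_grid()] the anchors refer to.
#' @param mesh the [build_quad_mesh()] of that grid.
#' @return numeric array (frames x points x 3), mm.
#' @export
track_homogeneous_point <- function(anchor, grid, mesh) {
  N <- shape_functions(anchor$r, anchor$s)
  e <- mesh$elements[anchor$element, , drop = FALSE]
  tt <- n_frames(grid)
  out <- array(NA_real_, c(tt, nrow(anchor), 3L))
  for (t in seq_len(tt)) {
    nodes <- frame_nodes(grid, t)
    for (k in 1:3)
      out[t, , k] <- rowSums(N * matrix(nodes[e, k], ncol = 4L))
  }
  out
}

#' Average tracked homogeneous trajectories into one model
#'
#' Takes the unweighted arithmetic mean over segmentations at every
#' (homogeneous point, frame) and repackages the result as a [motion_grid()]
#' on the homogeneous grid.
#'
#' @param tracked list of (frames x points x 3) arrays, one per segmentation,
#'   all of identical shape.
#' @param hg the [make_homogeneous_grid()] the trajectories live on.
#' @param segmentation_id identifier for the resulting model.
#' @return a [motion_grid()] with `n_H` x `m_H` nodes.
#' @export
average_models <- function(tracked, hg, segmentation_id = "averaged") {
  stopifnot(length(tracked) >= 1L)
  dims <- lapply(tracked, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("tracked trajectories differ in shape")
  acc <- tracked[[1]]
  if (length(tracked) > 1L)
    for (k in 2:length(tracked)) acc <- acc + tracked[[k]]
  acc <- acc / length(tracked)
  tt <- dim(acc)[1]
  pos <- array(NA_real_, c(tt, hg$n_H, hg$m_H, 3L))
  for (t in seq_len(tt))
    for (k in 1:3)
      pos[t, , , k] <- matrix(acc[t, , k], hg$n_H, hg$m_H, byrow = TRUE)
  motion_grid(pos, segmentation_id = segmentation_id)
}

#' Build an averaged wall-motion model from several segmentations
#'
#' Convenience wrapper running the full averaging chain: shared axis (from
#' the first segmentation's reference frame unless supplied), homogeneous
#' re-mesh, isoparametric tracking, averaging.
#'
#' @inheritParams make_homogeneous_grid
#' @param axis optional [fit_axis()] result; default fits the first
#'   segmentation's reference frame.
#' @return list with `model` (the averaged [motion_grid()]), `hg` (the
#'   homogeneous grid with anchors) and `axis`.
#' @export
average_segmentations <- function(segmentations, axis = NULL, n_H = NULL,
                                  m_H = 36L) {
  if (length(segmentations) < 2L)
    message("averaging a single segmentation: result is its homogeneous re-mesh")
  if (is.null(axis)) axis <- fit_axis(frame_nodes(segmentations[[1]], 1L))
  hg <- make_homogeneous_grid(segmentations, axis, n_H = n_H, m_H = m_H)
  tracked <- lapply(seq_along(segmentations), function(k)
    track_homogeneous_point(hg$per_seg[[k]]$anchor, segmentations[[k]],
                            hg$per_seg[[k]]$mesh))
  list(model = average_models(tracked, hg), hg = hg, axis = axis)
}
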