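#' Rigid and affine transform parameters
#'
#' `rigid_params()` describes a bounded rigid-body transform: rotations
#' `alpha`, `beta`, `gamma` (radians, applied as `Rx(alpha) Ry(beta)
#' Rz(gamma)`) and a translation `t` (mm).  `affine_params()` adds
#' anisotropic scales and shears; the linear part composes as
#' `M_s %*% M_r %*% M_h` (scale, rotation, shear).  The rotation/scale/shear
#' act about `center` (default the origin), which ICP sets to the moving
#' cloud's centroid so that parameter bounds stay interpretable.
#'
#' @param angles length-3 numeric, radians.
#' @param t length-3 translation, mm.
#' @param scales,shears length-3 scales (> 0) and length-6 shears
#'   `(h_xy, h_xz, h_yx, h_yz, h_zx, h_zy)`.
#' @param center rotation center, mm.
#' @return object of class `rigid_params` / `affine_params`.
#' @export
rigid_params <- function(angles = c(0, 0, 0), t = c(0, 0, 0),
                         center = c(0, 0, 0)) {
  stopifnot(length(angles) == 3L, length(t) == 3L, length(center) == 3L)
  structure(list(angles = as.numeric(angles), t = as.numeric(t),
                 center = as.numeric(center)),
            class = "rigid_params")
}

#' @rdname rigid_params
#' @export
affine_params <- function(angles = c(0, 0, 0), t = c(0, 0, 0),
                          scales = c(1, 1, 1), shears = numeric(6),
                          center = c(0, 0, 0)) {
  stopifnot(length(scales) == 3L, length(shears) == 6L)
  if (any(scales <= 0)) stop("scales must be positive")
  p <- rigid_params(angles, t, center)
  p$scales <- as.numeric(scales)
  p$shears <- as.numeric(shears)
  class(p) <- c("affine_params", "rigid_params")
  p
}

rotation_matrix <- function(angles) {
  ca <- cos(angles[1]); sa <- sin(angles[1])
  cb <- cos(angles[2]); sb <- sin(angles[2])
  cg <- cos(angles[3]); sg <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3L)
  Rz <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3L)
  Rx %*% Ry %*% Rz
}

#' Linear part of a transform
#'
#' Returns the 3 x 3 linear map of a parameter set: the rotation matrix for
#' rigid parameters, `M_s %*% M_r %*% M_h` for affine ones.
#'
#' @param params a [rigid_params()] or [affine_params()].
#' @return 3 x 3 matrix.
#' @export
transform_matrix <- function(params) {
  M <- rotation_matrix(params$angles)
  if (inherits(params, "affine_params")) {
    h <- params$shears
    Mh <- matrix(c(1, h[3], h[5], h[1], 1, h[6], h[2], h[4], 1), 3L)
    M <- diag(params$scales) %*% M %*% Mh
  }
  M
}

#' Apply a transform to a point cloud
#'
#' Maps every point by `p -> M (p - center) + center + t` with `M` from
#' [transform_matrix()].
#'
#' @param params a [rigid_params()] or [affine_params()].
#' @param cloud a [point_cloud()] or plain (points x 3) matrix.
#' @return transformed cloud of the same type.
#' @export
apply_transform <- function(params, cloud) {
  M <- transform_matrix(params)
  pts <- as.matrix(cloud)
  out <- sweep(pts, 2L, params$center) %*% t(M)
  out <- sweep(out, 2L, params$center + params$t, "+")
  if (inherits(cloud, "point_cloud")) point_cloud(out, attr(cloud, "label"))
  else out
}

#' Nearest-neighbour correspondence between two clouds
#'
#' For every moving point, the index of the Euclidean-nearest static point
#' (k-d tree search; distance ties resolve to the lowest static index).
#'
#' @param moving,static point matrices / [point_cloud()]s.
#' @return list with integer `index` and numeric `distance` vectors.
#' @export
nearest_pairs <- function(moving, static) {
  r <- nn_query(as.matrix(static), as.matrix(moving), 1L)
  list(index = as.integer(r$index[, 1]), distance = as.numeric(r$distance[, 1]))
}

#' Cloud-to-cloud error metrics
#'
#' `cloud_rmse()` is the root-mean-squared nearest-pair distance from the
#' moving to the static cloud (the direction in which the ICP objective sums
#' its residuals).  `cloud_hausdorff()` is the symmetric Hausdorff distance,
#' the larger of the two directed maximum nearest-neighbour distances; both
#' directed values are also returned.
#'
#' @param moving,static point matrices / [point_cloud()]s.
#' @return `cloud_rmse()`: a scalar (mm).  `cloud_hausdorff()`: list
#'   `symmetric`, `moving_to_static`, `static_to_moving` (mm).
#' @export
cloud_rmse <- function(moving, static) {
  sqrt(mean(nearest_pairs(moving, static)$distance^2))
}

#' @rdname cloud_rmse
#' @export
cloud_hausdorff <- function(moving, static) {
  d1 <- max(nearest_pairs(moving, static)$distance)
  d2 <- max(nearest_pairs(static, moving)$distance)
  list(symmetric = max(d1, d2), moving_to_static = d1, static_to_moving = d2)
}

#' Default ICP parameter bounds
#'
#' Rotations are limited to +-30 degrees, translations (about the centroid
#' initialisation) to +-20 mm, scales to [0.8, 1.2] and shears to +-0.2.
#' Limiting the parameter space avoids unphysiological registrations of
#' nearly symmetric fusiform aneurysm geometries.
#'
#' @param rot_deg,trans_mm,scale_range,shear symmetric limits.
#' @return list used by [icp()].
#' @export
icp_bounds <- function(rot_deg = 30, trans_mm = 20,
                       scale_range = c(0.8, 1.2), shear = 0.2) {
  list(rot = rot_deg * pi / 180, trans = trans_mm,
       scale = scale_range, shear = shear)
}

pack_params <- function(params, mode) {
  if (mode == "rigid") c(params$angles, params$t)
  else c(params$angles, params$t, params$scales, params$shears)
}

unpack_params <- function(p, mode, center) {
  if (mode == "rigid") rigid_params(p[1:3], p[4:6], center)
  else affine_params(p[1:3], p[4:6], p[7:9], p[10:15], center)
}

#' Iterative closest point registration
#'
#' Aligns a moving (ultrasound) cloud to a static (CT) cloud by alternating
#' nearest-neighbour correspondence with a bounded nonlinear least-squares
#' update of the transform parameters (Levenberg-Marquardt with box
#' constraints), until the RMSE changes by less than `tol` mm or `max_iter`
#' iterations.  The translation is initialised so that the two centroids
#' coincide; rotation (and scale/shear) act about the moving centroid.
#'
#' @param moving,static point matrices / [point_cloud()]s.
#' @param mode `"rigid"` or `"affine"`.  Affine registration is initialised
#'   from the rigid solution, which stabilises the nine extra parameters.
#' @param bounds an [icp_bounds()] list.
#' @param init optional initial [rigid_params()]/[affine_params()] (its
#'   angles/scales/shears seed the search; translation is re-centred).
#' @param tol RMSE convergence tolerance, mm.
#' @param max_iter maximum correspondence iterations.
#' @return object of class `registration_result`: `params`, `final_rmse`,
#'   `hausdorff` (list, see [cloud_hausdorff()]), `iterations`, `converged`,
#'   `rmse_trace`.
#' @export
icp <- function(moving, static, mode = c("rigid", "affine"),
                bounds = icp_bounds(), init = NULL, tol = 1e-6,
                max_iter = 100L) {
  mode <- match.arg(mode)
  moving <- as.matrix(moving)
  static <- as.matrix(static)
  if (nrow(static) < 4L) stop("static cloud is degenerate (< 4 points)")
  if (mode == "affine" && (is.null(init) || !inherits(init, "affine_params"))) {
    rig <- icp(moving, static, "rigid", bounds = bounds, init = init,
               tol = tol, max_iter = max_iter)
    init <- affine_params(rig$params$angles, rig$params$t,
                          center = rig$params$center)
  }
  center <- colMeans(moving)
  t0 <- colMeans(static) - center
  if (is.null(init)) {
    p <- c(0, 0, 0, t0)
  } else {
    p <- pack_params(init, mode)
    p[4:6] <- if (all(init$t == 0)) t0 else init$t
  }
  if (mode == "affine" && length(p) == 6L) p <- c(p, 1, 1, 1, numeric(6))
  lower <- c(rep(-bounds$rot, 3), t0 - bounds$trans)
  upper <- c(rep(bounds$rot, 3), t0 + bounds$trans)
  if (mode == "affine") {
    lower <- c(lower, rep(bounds$scale[1], 3), rep(-bounds$shear, 6))
    upper <- c(upper, rep(bounds$scale[2], 3), rep(bounds$shear, 6))
  }
  p <- pmin(pmax(p, lower), upper)

  resid_fun <- function(par, target) {
    tr <- apply_transform(unpack_params(par, mode, center), moving)
    as.numeric(tr - target)
  }
  rmse_trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    tr <- apply_transform(unpack_params(p, mode, center), moving)
    pr <- nearest_pairs(tr, static)
    target <- static[pr$index, , drop = FALSE]
    fit <- minpack.lm::nls.lm(
      par = p, lower = lower, upper = upper, fn = resid_fun, target = target,
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 200L))
    p <- as.numeric(fit$par)
    tr <- apply_transform(unpack_params(p, mode, center), moving)
    cur <- sqrt(mean(nearest_pairs(tr, static)$distance^2))
    rmse_trace <- c(rmse_trace, cur)
    if (abs(prev - cur) < tol) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  params <- unpack_params(p, mode, center)
  tr <- apply_transform(params, moving)
  structure(list(params = params,
                 final_rmse = sqrt(mean(nearest_pairs(tr, static)$distance^2)),
                 hausdorff = cloud_hausdorff(tr, static),
                 iterations = it, converged = converged,
                 rmse_trace = rmse_trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> rmse %.4g mm, Hausdorff %.4g mm, %d iterations%s\n",
              x$final_rmse, x$hausdorff$symmetric, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Register every frame and keep the best
#'
#' The cardiac phase of the CT acquisition is unknown, so every ultrasound
#' frame is registered to the CT wall cloud independently and the frame with
#' the smallest final RMSE is selected (ties go to the earliest frame).
#'
#' @param grid a [motion_grid()].
#' @param static the CT wall [point_cloud()].
#' @param mode,bounds,init,tol,max_iter passed to [icp()].
#' @return list `best_frame` (index), `best` (its registration), `per_frame`
#'   (list of [icp()] results).
#' @export
select_best_frame <- function(grid, static, mode = "rigid",
                              bounds = icp_bounds(), init = NULL, tol = 1e-6,
                              max_iter = 100L) {
  tt <- n_frames(grid)
  per_frame <- vector("list", tt)
  for (t in seq_len(tt)) {
    per_frame[[t]] <- icp(frame_nodes(grid, t), static, mode = mode,
                          bounds = bounds, init = init, tol = tol,
                          max_iter = max_iter)
  }
  rmses <- vapply(per_frame, function(r) r$final_rmse, numeric(1))
  best <- which.min(rmses)
  list(best_frame = best, best = per_frame[[best]], per_frame = per_frame,
       rmse = rmses)
}
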