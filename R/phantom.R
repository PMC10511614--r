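#' Specification of a pulsating aneurysm phantom
#'
#' Defines a fusiform abdominal-aortic-aneurysm phantom with known ground
#' truth, emulating the tracked-point export of a 4D ultrasound
#' acquisition.  The wall surface is a tube of radius profile
#' `rho(x, phi) = rho0 + a exp(-(x - x0)^2 / (2 sigma_b^2)) (1 + asym cos(phi - phi_asym))`
#' pulsating radially as `r(x, phi, t) = rho(x, phi) (1 + A c(x, phi) w(t))`
#' with the cardiac waveform `w(t) = (1 - cos(2 pi t / T)) / 2` and a
#' compliance map `c` that drops to the factor `kappa` inside calcified
#' patches.  Defaults describe a typical imaged AAA: base radius 15 mm with
#' a 10 mm bulge (peak diameter ~50 mm), 50 mm imaged length, a 14 x 36
#' node grid (504 tracked points), 20 frames per cycle, peak circumferential
#' strain 1.2% and a 25% strain reduction (kappa = 0.75) inside two
#' calcified patches.  The mild azimuthal bulge modulation (`asym`) keeps
#' the shape fusiform but, like a real aneurysm, not perfectly rotationally
#' symmetric.
#'
#' @param rho0 base radius, mm.
#' @param bulge_a,bulge_x0,bulge_sigma bulge amplitude (mm), centre and
#'   Gaussian width (mm) along the axis.
#' @param asym,phi_asym relative azimuthal modulation of the bulge and its
#'   phase (radians).
#' @param length vessel length, mm.
#' @param n,m grid heights and circumferential points.
#' @param frames frames per cardiac cycle.
#' @param A peak circumferential strain (fraction).
#' @param kappa compliance factor of calcified patches, in (0, 1].
#' @param calc_patches list of patches, each `list(x = c(lo, hi), phi =
#'   c(lo, hi))` in mm / radians.
#' @param axial_frac optional axial strain as a fraction of `A` (0 disables
#'   axial motion).
#' @param sigma_n segmentation node noise standard deviation, mm (used by
#'   [make_segmentations()]).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(rho0 = 15, bulge_a = 10, bulge_x0 = 22.5,
                         bulge_sigma = 12, asym = 0.2, phi_asym = 0.7,
                         length = 50, n = 14L, m = 36L, frames = 20L,
                         A = 0.012, kappa = 0.75,
                         calc_patches = list(
                           list(x = c(8, 24), phi = c(-2.5, -0.5)),
                           list(x = c(26, 42), phi = c(0.4, 2.4))),
                         axial_frac = 0, sigma_n = 0.3) {
  spec <- list(rho0 = rho0, bulge_a = bulge_a, bulge_x0 = bulge_x0,
               bulge_sigma = bulge_sigma, asym = asym, phi_asym = phi_asym,
               length = length, n = as.integer(n), m = as.integer(m),
               frames = as.integer(frames), A = A, kappa = kappa,
               calc_patches = calc_patches, axial_frac = axial_frac,
               sigma_n = sigma_n)
  with(spec, {
    stopifnot(rho0 > 0, length > 0, bulge_sigma > 0, n >= 2L, m >= 3L,
              frames >= 2L, A >= 0, A < 0.2, kappa > 0, kappa <= 1,
              sigma_n >= 0, asym >= 0, asym < 1)
  })
  structure(spec, class = "phantom_spec")
}

## radius profile, waveform and compliance field of a phantom
phantom_rho <- function(spec, x, phi) {
  spec$rho0 + spec$bulge_a * exp(-(x - spec$bulge_x0)^2 /
                                   (2 * spec$bulge_sigma^2)) *
    (1 + spec$asym * cos(phi - spec$phi_asym))
}

phantom_waveform <- function(spec, t0) {       # t0 is 0-based frame index
  (1 - cos(2 * pi * t0 / spec$frames)) / 2
}

in_patch <- function(spec, x, phi) {
  phi <- ((phi + pi) %% (2 * pi)) - pi
  hit <- rep(FALSE, max(length(x), length(phi)))
  for (p in spec$calc_patches)
    hit <- hit | (x >= p$x[1] & x <= p$x[2] & phi >= p$phi[1] & phi <= p$phi[2])
  hit
}

phantom_compliance <- function(spec, x, phi) {
  ifelse(in_patch(spec, x, phi), spec$kappa, 1)
}

## surface position at axial station x, angle phi, 0-based frame t0
phantom_surface <- function(spec, x, phi, t0) {
  r <- phantom_rho(spec, x, phi) *
    (1 + spec$A * phantom_compliance(spec, x, phi) * phantom_waveform(spec, t0))
  xx <- x + spec$axial_frac * spec$A * phantom_waveform(spec, t0) *
    (x - spec$length / 2)
  cbind(x = xx, y = r * cos(phi), z = r * sin(phi))
}

#' Generate a phantom acquisition with ground truth
#'
#' Places the grid nodes of a [phantom_spec()] on the pulsating surface for
#' every frame and records per-element ground truth: the compliance at the
#' element (mean over its nodes), the true circumferential and longitudinal
#' peak-to-peak amplitudes, and the calcified flag (all four nodes inside a
#' patch).  Because every circumferential chord between nodes of equal
#' compliance scales exactly with the local radius, the true circumferential
#' amplitude of an interior element is exactly `A * c * (max w - min w)`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth`: `grid` (noise-free
#'   [motion_grid()]), `mesh`, `elements` data.frame (`compliance`,
#'   `amp22_true`, `amp11_true`, `calcified`), node angle/station layout,
#'   and the spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  xs <- seq(0, spec$length, length.out = spec$n)
  phis <- -pi + (seq_len(spec$m) - 0.5) * 2 * pi / spec$m
  gg <- expand.grid(phi = phis, x = xs)        # j fastest, matching node ids
  pos <- array(NA_real_, c(spec$frames, spec$n, spec$m, 3L))
  for (t in seq_len(spec$frames)) {
    s <- phantom_surface(spec, gg$x, gg$phi, t - 1L)
    for (k in 1:3) pos[t, , , k] <- matrix(s[, k], spec$n, spec$m, byrow = TRUE)
  }
  grid <- motion_grid(pos, segmentation_id = "phantom_truth")
  mesh <- build_quad_mesh(grid)
  ## per-element truth from the node layout
  e <- mesh$elements
  node_x <- rep(xs, each = spec$m)
  node_phi <- rep(phis, times = spec$n)
  node_in <- in_patch(spec, node_x, node_phi)
  node_c <- phantom_compliance(spec, node_x, node_phi)
  c_el <- rowMeans(matrix(node_c[e], ncol = 4L))
  calc_el <- rowSums(matrix(node_in[e], ncol = 4L)) == 4L
  wrange <- diff(range(phantom_waveform(spec, seq_len(spec$frames) - 1L)))
  amp22 <- spec$A * c_el * wrange
  ## longitudinal truth: meridian arc-length change from the radius slope
  ex <- (node_x[e[, 1]] + node_x[e[, 4]]) / 2
  ephi <- node_phi[e[, 1]]
  h <- 1e-4
  drho <- (phantom_rho(spec, ex + h, ephi) - phantom_rho(spec, ex - h, ephi)) /
    (2 * h)
  lam1 <- sqrt(1 + (drho * (1 + spec$A * c_el * wrange))^2) /
    sqrt(1 + drho^2)
  amp11 <- (lam1 - 1) + spec$axial_frac * spec$A * wrange
  structure(list(grid = grid, mesh = mesh,
                 elements = data.frame(element = seq_len(nrow(e)),
                                       compliance = c_el,
                                       amp22_true = amp22,
                                       amp11_true = amp11,
                                       calcified = calc_el),
                 node_x = node_x, node_phi = node_phi, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d grid, %d frames, %d/%d calcified elements\n",
              x$spec$n, x$spec$m, x$spec$frames, sum(x$elements$calcified),
              nrow(x$elements)))
  invisible(x)
}

## smooth random field on (x, phi): constant + first axial/angular harmonics
bias_field <- function(spec, x, phi, amp, rng_coef) {
  xn <- 2 * pi * x / spec$length
  basis <- cbind(1, sqrt(2) * sin(xn), sqrt(2) * cos(xn),
                 sqrt(2) * sin(phi), sqrt(2) * cos(phi))
  amp * as.numeric(basis %*% rng_coef) / sqrt(length(rng_coef))
}

#' Simulate noisy manual segmentations of a phantom
#'
#' Emulates repeated manual segmentation plus speckle tracking of one
#' acquisition: each segmentation is the ground-truth motion (resampled to
#' its own grid dimensions when they differ from the truth grid) with
#' i.i.d. Gaussian node noise of standard deviation `sigma_n` drawn
#' independently per segmentation and frame, plus a smooth per-segmentation
#' bias field (amplitude `sigma_n / 2`, constant over the cycle) that mimics
#' observer-dependent masking differences.
#'
#' @param truth a [generate_phantom()] result.
#' @param K number of segmentations.
#' @param sigma_n node noise sd in mm; defaults to the spec value.
#' @param dims optional list of `c(n, m)` per segmentation; default: the
#'   truth dimensions for all.
#' @param seed RNG seed (integer) for reproducibility.
#' @return list of `K` [motion_grid()] objects.
#' @export
make_segmentations <- function(truth, K = 10L, sigma_n = NULL, dims = NULL,
                               seed = 1L) {
  spec <- truth$spec
  if (is.null(sigma_n)) sigma_n <- spec$sigma_n
  if (K < 1L) stop("K must be at least 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  axis <- NULL
  out <- vector("list", K)
  for (k in seq_len(K)) {
    dk <- if (is.null(dims)) c(spec$n, spec$m) else dims[[k]]
    if (all(dk == c(spec$n, spec$m))) {
      base <- truth$grid$positions
    } else {
      if (is.null(axis)) axis <- fit_axis(frame_nodes(truth$grid, 1L))
      base <- resample_truth(truth, dk[1], dk[2], axis)
    }
    tt <- dim(base)[1]
    noisy <- base + array(rnorm(length(base), sd = sigma_n), dim(base))
    ## smooth observer bias, constant over frames
    nx <- if (all(dk == c(spec$n, spec$m))) truth$node_x else
      attr(base, "node_x")
    nphi <- if (all(dk == c(spec$n, spec$m))) truth$node_phi else
      attr(base, "node_phi")
    for (coord in 1:3) {
      b <- bias_field(spec, nx, nphi, sigma_n / 2, rnorm(5L))
      bmat <- matrix(b, dk[1], dk[2], byrow = TRUE)
      for (t in seq_len(tt)) noisy[t, , , coord] <- noisy[t, , , coord] + bmat
    }
    out[[k]] <- motion_grid(noisy, segmentation_id = sprintf("seg%02d", k))
  }
  out
}

## resample the truth surface motion onto an n2 x m2 grid via the reference
## interpolant and isoparametric tracking
resample_truth <- function(truth, n2, m2, axis) {
  surf <- interpolate_reference_surface(truth$grid, axis)
  uw <- attr(surf, "unwrapped")
  mesh <- attr(surf, "mesh")
  lo <- min(rowMeans(uw$x)); hi <- max(rowMeans(uw$x))
  pad <- (hi - lo) / (2 * (n2 - 1))
  xt <- seq(lo + pad, hi - pad, length.out = n2)
  pt <- -pi + (seq_len(m2) - 0.5) * 2 * pi / m2
  tg <- expand.grid(phi = pt, x_long = xt)[, c("x_long", "phi")]
  anchor <- locate_in_element(tg, uw, mesh)
  traj <- track_homogeneous_point(anchor, truth$grid, mesh)
  tt <- dim(traj)[1]
  pos <- array(NA_real_, c(tt, n2, m2, 3L))
  for (t in seq_len(tt))
    for (k in 1:3) pos[t, , , k] <- matrix(traj[t, , k], n2, m2, byrow = TRUE)
  attr(pos, "node_x") <- rep(xt, each = m2)
  attr(pos, "node_phi") <- rep(pt, times = n2)
  pos
}

#' Sample CT-like wall and calcification clouds from a phantom
#'
#' Draws area-uniform point samples of the phantom surface at one frame (the
#' wall cloud) and of the calcified patches only (the calcification cloud),
#' applies a known rigid or affine transform to both, and adds isotropic
#' Gaussian jitter.  This emulates the CT-angiography reconstruction that
#' the ultrasound geometry is registered to, with the transform as
#' registration ground truth.
#'
#' @param truth a [generate_phantom()] result.
#' @param frame 1-based frame index sampled.
#' @param density wall sampling density, points per mm^2.
#' @param calc_density calcification sampling density, points per mm^2.
#' @param transform a [rigid_params()]/[affine_params()] applied to both
#'   clouds (default identity).
#' @param jitter_sd isotropic jitter sd in mm.
#' @param seed RNG seed.
#' @return list with `wall` and `calcification` [point_cloud()]s and the
#'   `transform` applied.
#' @export
make_ct_clouds <- function(truth, frame = 1L, density = 2, calc_density = 4,
                           transform = rigid_params(), jitter_sd = 0,
                           seed = 1L) {
  spec <- truth$spec
  if (frame < 1L || frame > spec$frames) stop("frame out of range")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  sample_surface <- function(n_target, keep_fun) {
    got <- matrix(numeric(0), 0L, 3L)
    rho_max <- max(phantom_rho(spec, seq(0, spec$length, length.out = 200),
                               spec$phi_asym))
    guard <- 0L
    while (nrow(got) < n_target && guard < 60L) {
      guard <- guard + 1L
      nb <- 2L * (n_target - nrow(got)) + 16L
      x <- runif(nb, 0, spec$length)
      phi <- runif(nb, -pi, pi)
      ## accept with probability proportional to the local area element
      rho <- phantom_rho(spec, x, phi)
      h <- 1e-3
      slope <- (phantom_rho(spec, x + h, phi) - phantom_rho(spec, x - h, phi)) /
        (2 * h)
      w <- rho * sqrt(1 + slope^2)
      acc <- runif(nb) < w / (rho_max * sqrt(1 + max(abs(slope))^2) + 1e-12)
      keep <- acc & keep_fun(x, phi)
      got <- rbind(got, phantom_surface(spec, x[keep], phi[keep], frame - 1L))
    }
    got[seq_len(min(nrow(got), n_target)), , drop = FALSE]
  }
  area <- 2 * pi * mean(phantom_rho(spec, seq(0, spec$length, length.out = 200),
                                    0)) * spec$length
  wall <- sample_surface(max(round(density * area), 200L),
                         function(x, phi) rep(TRUE, length(x)))
  patch_area <- sum(vapply(spec$calc_patches, function(p)
    diff(p$x) * diff(p$phi) * mean(phantom_rho(spec, mean(p$x), mean(p$phi))),
    numeric(1)))
  calc <- sample_surface(max(round(calc_density * patch_area), 20L),
                         function(x, phi) in_patch(spec, x, phi))
  if (jitter_sd > 0) {
    wall <- wall + matrix(rnorm(length(wall), sd = jitter_sd), nrow(wall))
    calc <- calc + matrix(rnorm(length(calc), sd = jitter_sd), nrow(calc))
  }
  list(wall = point_cloud(apply_transform(transform, wall), "wall"),
       calcification = point_cloud(apply_transform(transform, calc),
                                   "calcification"),
       transform = transform)
}
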