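#' Calcification coverage fraction of wall elements
#'
#' Samples every element on a 10 x 10 lattice of interior `(r, s)` points
#' (via the bilinear shape functions) and returns, per element, the fraction
#' of sample points lying within `capture_radius` of any calcification
#' point.  Element node positions should be taken from the best-registered
#' frame after affine registration so that ultrasound elements and the CT
#' calcification cloud share one coordinate frame.
#'
#' @param mesh a [build_quad_mesh()].
#' @param nodes node coordinate matrix of the registered frame (rows follow
#'   node ids), mm.
#' @param calc_cloud calcification [point_cloud()] (may have zero rows via
#'   `NULL`, giving coverage 0).
#' @param capture_radius capture distance in mm; default half the median
#'   nearest-neighbour spacing of the calcification cloud.
#' @param lattice number of sample points per local direction.
#' @return numeric vector of coverage fractions in [0, 1], one per element.
#' @export
coverage_fraction <- function(mesh, nodes, calc_cloud,
                              capture_radius = NULL, lattice = 10L) {
  nel <- nrow(mesh$elements)
  if (is.null(calc_cloud) || nrow(calc_cloud) == 0L) return(numeric(nel))
  calc <- as.matrix(calc_cloud)
  if (is.null(capture_radius)) capture_radius <- median_spacing(calc) / 2
  if (capture_radius <= 0) stop("capture_radius must be positive")
  rs <- seq(-1 + 1 / lattice, 1 - 1 / lattice, length.out = lattice)
  gg <- expand.grid(r = rs, s = rs)
  N <- shape_functions(gg$r, gg$s)              # (lattice^2 x 4)
  e <- mesh$elements
  ## sample points of all elements at once: (nel * lattice^2) x 3
  samp <- matrix(0, nel * nrow(gg), 3L)
  for (k in 1:3) {
    Xa <- matrix(nodes[e, k], ncol = 4L)        # nel x 4
    samp[, k] <- as.numeric(tcrossprod(Xa, N))  # nel x lattice^2, col-major
  }
  d <- nn_query(calc, samp, 1L)$distance[, 1]
  hit <- matrix(d <= capture_radius, nel, nrow(gg))
  rowMeans(hit)
}

## median nearest-neighbour distance within one cloud
median_spacing <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(Inf)
  median(nn_query(pts, pts, 2L)$distance[, 2])
}

#' Classify wall elements as calcified or non-calcified
#'
#' An element is calcified when at least `threshold` (default half) of its
#' area is covered by calcification, estimated by [coverage_fraction()].
#' Connected patches of calcified elements smaller than
#' `min_patch_elements` are cleared back to non-calcified: calcifications
#' too small to cover one element are neglected.  Connectivity is
#' 4-neighbour on the element grid and wraps circumferentially.
#'
#' @inheritParams coverage_fraction
#' @param threshold area-coverage threshold for the calcified label.
#' @param min_patch_elements minimum size of a connected calcified patch.
#' @return data.frame with columns `element`, `coverage`, `calcified`.
#' @export
classify_elements <- function(mesh, nodes, calc_cloud, threshold = 0.5,
                              capture_radius = NULL, min_patch_elements = 1L,
                              lattice = 10L) {
  cov <- coverage_fraction(mesh, nodes, calc_cloud, capture_radius, lattice)
  calc <- cov >= threshold
  if (min_patch_elements > 1L && any(calc)) {
    comp <- element_components(mesh, calc)
    keep <- table(comp[calc])
    small <- as.integer(names(keep)[keep < min_patch_elements])
    calc[comp %in% small] <- FALSE
  }
  data.frame(element = seq_along(cov), coverage = cov, calcified = calc)
}

## connected components (4-neighbourhood, circumferential wrap) over the
## element grid restricted to `mask`; 0 outside the mask
element_components <- function(mesh, mask) {
  ni <- mesh$n - 1L; nj <- mesh$m
  lab <- integer(length(mask))
  idx <- function(i, j) (i - 1L) * nj + ((j - 1L) %% nj) + 1L
  comp <- 0L
  for (start in which(mask & lab == 0L)) {
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %/% nj + 1L
      j <- (cur - 1L) %% nj + 1L
      nb <- c(if (i > 1L) idx(i - 1L, j), if (i < ni) idx(i + 1L, j),
              idx(i, j - 1L), idx(i, j + 1L))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Distribution indices of strain-amplitude regions
#'
#' Summarises the per-element peak-to-peak amplitude distribution of each
#' strain component within the calcified and non-calcified regions: mean and
#' maximum strain (in %), local strain ratio (max / mean), heterogeneity
#' index (coefficient of variation, sample standard deviation / mean), plus
#' median and quartiles.  Ratio and heterogeneity are reported as `NA` when
#' undefined (zero mean, or fewer than two elements for the standard
#' deviation).  Degenerate elements are excluded.
#'
#' @param amplitudes a [strain_amplitudes()] data.frame.
#' @param labels a [classify_elements()] data.frame (same element order).
#' @return data.frame with one row per component x region.
#' @export
distribution_indices <- function(amplitudes, labels) {
  stopifnot(nrow(amplitudes) == nrow(labels))
  keep <- !amplitudes$degenerate
  rows <- list()
  for (comp in c("11", "22")) {
    a <- amplitudes[[paste0("amp", comp)]]
    for (region in c("calcified", "non_calcified")) {
      sel <- keep & (labels$calcified == (region == "calcified"))
      v <- a[sel] * 100   # report in %
      n <- length(v)
      mean_v <- if (n) mean(v) else NA_real_
      max_v <- if (n) max(v) else NA_real_
      ratio <- if (n && mean_v != 0) max_v / mean_v else NA_real_
      het <- if (n >= 2L && mean_v != 0) sd(v) / mean_v else NA_real_
      qq <- if (n) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
            else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        component = paste0("eps", comp), region = region, n = n,
        mean_pct = mean_v, max_pct = max_v, strain_ratio = ratio,
        heterogeneity = het, q1_pct = qq[1], median_pct = qq[2],
        q3_pct = qq[3])
    }
  }
  do.call(rbind, rows)
}

#' One-sided (left-tail) Mann-Whitney U test for calcified regions
#'
#' Tests the null of equal amplitude medians in calcified and non-calcified
#' wall regions against the alternative that the calcified median is
#' smaller.  The exact null distribution is used for combined sample sizes
#' up to 20 without ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param calc_amps,nocalc_amps numeric amplitude vectors of the calcified
#'   and non-calcified elements.
#' @return list with `U`, `p_value`, `n_calc`, `n_nocalc`, `method` and a
#'   significance `stars` string (`*`, `**`, `***` at the 5%, 1% and 0.1%
#'   levels).
#' @export
mannwhitney_left <- function(calc_amps, nocalc_amps) {
  if (!length(calc_amps) || !length(nocalc_amps))
    stop("both regions must contain at least one element")
  n1 <- length(calc_amps); n2 <- length(nocalc_amps)
  ties <- anyDuplicated(c(calc_amps, nocalc_amps)) > 0L
  use_exact <- (n1 + n2 <= 20L) && !ties
  ht <- suppressWarnings(
    wilcox.test(calc_amps, nocalc_amps, alternative = "less",
                exact = use_exact, correct = TRUE))
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(U = unname(ht$statistic), p_value = p, n_calc = n1, n_nocalc = n2,
       method = if (use_exact) "exact" else "normal approximation",
       stars = stars)
}

#' Kolmogorov-Smirnov check against a fitted normal
#'
#' One-sample KS test of a sample against a normal distribution with the
#' sample's own mean and standard deviation (plain KS, no Lilliefors
#' correction, matching common packaged behaviour).  Used only to justify
#' the nonparametric regional comparison; the outcome is informational.
#'
#' @param sample numeric vector, `n >= 5`.
#' @param alpha significance level for the `normal` flag.
#' @return list with `statistic`, `p_value`, `normal` (not rejected at
#'   `alpha`).
#' @export
ks_normality <- function(sample, alpha = 0.05) {
  if (length(sample) < 5L) stop("need at least 5 observations")
  ht <- suppressWarnings(ks.test(sample, "pnorm", mean(sample), sd(sample)))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       normal = ht$p.value >= alpha)
}
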