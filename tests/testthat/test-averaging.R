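test_that("shape functions satisfy partition of unity and nodal interpolation", {
  expect_equal(as.numeric(shape_functions(0, 0)), rep(0.25, 4))
  corners <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  for (a in 1:4) {
    w <- as.numeric(shape_functions(corners[a, 1], corners[a, 2]))
    expect_equal(w, as.numeric(1:4 == a))       # exact Kronecker property
  }
  set.seed(1)
  r <- runif(200, -1.5, 1.5); s <- runif(200, -1.5, 1.5)
  expect_equal(rowSums(shape_functions(r, s)), rep(1, 200))  # exact
})

test_that("inverse bilinear mapping matches the affine closed form and round-trips", {
  ## axis-aligned rectangle (0,0),(2,0),(2,1),(0,1): the inverse is affine.
  ## In stored node order the circumferential (r) direction is the second
  ## coordinate pair: nodes (0,0),(2,0) span r, (0,1) spans s.
  xn <- matrix(c(0, 2, 2, 0), 1, 4)
  yn <- matrix(c(0, 0, 1, 1), 1, 4)
  inv <- aaastrain:::inverse_bilinear(xn, yn, 0.5, 0.25)
  expect_true(inv$converged)
  expect_equal(c(inv$r, inv$s), c(-0.5, -0.5), tolerance = 1e-9)
  ## element centroid maps to (0, 0)
  inv0 <- aaastrain:::inverse_bilinear(xn, yn, 1, 0.5)
  expect_equal(c(inv0$r, inv0$s), c(0, 0), tolerance = 1e-12)
  ## general warped quads: forward map of the result reproduces the query
  set.seed(5)
  for (rep in 1:20) {
    qx <- c(0, 1, 1.2, -0.1) + rnorm(4, sd = 0.08)
    qy <- c(0, 0.1, 1, 0.9) + rnorm(4, sd = 0.08)
    px <- runif(1, 0.3, 0.7); py <- runif(1, 0.3, 0.7)
    iv <- aaastrain:::inverse_bilinear(rbind(qx), rbind(qy), px, py)
    expect_true(iv$converged)
    f <- aaastrain:::bilinear_map(rbind(qx), rbind(qy), iv$r, iv$s)
    expect_lt(abs(f$x - px) + abs(f$y - py), 1e-9)
  }
})

test_that("reference-surface interpolation reproduces knots and linear profiles", {
  ax <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  ## perfect cylinder: R identically 10 everywhere
  g <- tube_grid(n = 6, m = 36, radius = 10, len = 40)
  surf <- interpolate_reference_surface(g, ax)
  set.seed(2)
  q <- surf(runif(50, 5, 35), runif(50, -pi, pi))
  expect_equal(q$R, rep(10, 50), tolerance = 1e-9)
  ## querying an existing node returns that node exactly
  uw <- attr(surf, "unwrapped")
  node <- surf(uw$x[3, 7], uw$phi[3, 7])
  expect_equal(as.numeric(node[, c("x", "y", "z")]),
               frame_nodes(g, 1)[(3 - 1) * 36 + 7, ], tolerance = 1e-10)
  ## cone: linear radius in x -> midpoint query is the mean of ring radii
  gc <- tube_grid(n = 6, m = 36, radius = function(x) 8 + 0.1 * x, len = 40)
  surfc <- interpolate_reference_surface(gc, ax)
  uwc <- attr(surfc, "unwrapped")
  xm <- (uwc$x[2, 4] + uwc$x[3, 4]) / 2
  got <- surfc(xm, uwc$phi[2, 4])$R
  expect_equal(got, (uwc$R[2, 4] + uwc$R[3, 4]) / 2, tolerance = 1e-10)
  ## queries outside the axial range fail loudly
  expect_error(surf(1e3, 0), "no element")
})

test_that("homogeneous grids coincide for identical segmentations and resolve radii", {
  ax <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  g <- tube_grid(n = 8, m = 36, radius = 10, len = 40, frames = 3)
  hg <- make_homogeneous_grid(list(g, g, g), ax, n_H = 5)
  expect_equal(nrow(hg$targets), 5 * 36)
  for (k in 2:3)
    expect_equal(hg$per_seg[[k]]$ref, hg$per_seg[[1]]$ref, tolerance = 1e-12)
  ## two coaxial cylinders: per-segmentation reference radii stay 10 and 12
  g12 <- tube_grid(n = 6, m = 36, radius = 12, len = 40, frames = 3)
  hg2 <- make_homogeneous_grid(list(g, g12), ax, n_H = 4)
  r1 <- sqrt(rowSums(hg2$per_seg[[1]]$ref[, 1:2]^2))
  r2 <- sqrt(rowSums(hg2$per_seg[[2]]$ref[, 1:2]^2))
  expect_equal(r1, rep(10, length(r1)), tolerance = 1e-9)
  expect_equal(r2, rep(12, length(r2)), tolerance = 1e-9)
  ## anchors are inside elements and reproduce the reference within 1e-9
  for (k in 1:2) {
    a <- hg2$per_seg[[k]]$anchor
    expect_true(all(abs(a$r) <= 1 + 1e-6 & abs(a$s) <= 1 + 1e-6))
  }
  ## disjoint axial ranges are rejected
  gfar <- tube_grid(n = 6, m = 36, radius = 10, len = 40, frames = 3,
                    center = c(0, 0, 200))
  expect_error(make_homogeneous_grid(list(g, gfar), ax), "common axial")
})

test_that("isoparametric tracking follows translation, scaling and corners", {
  ax <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  g <- tube_grid(n = 6, m = 36, radius = 10, len = 40, frames = 2)
  ## frame 2: rigid translation by d
  d <- c(1.5, -2, 0.5)
  g$positions[2, , , ] <- g$positions[1, , , ]
  for (k in 1:3) g$positions[2, , , k] <- g$positions[2, , , k] + d[k]
  hg <- make_homogeneous_grid(list(g, g), ax, n_H = 4)
  tr <- track_homogeneous_point(hg$per_seg[[1]]$anchor, g, hg$per_seg[[1]]$mesh)
  expect_equal(tr[1, , ], hg$per_seg[[1]]$ref, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(tr[2, , ], sweep(tr[1, , ], 2, d, "+"), tolerance = 1e-12,
               ignore_attr = TRUE)

  ## uniform scaling of a planar element about its centroid moves the
  ## tracked point radially from the centroid by the same factor
  ref <- embed_element(unit_element(2, 1))
  cur <- sweep(sweep(ref, 2, colMeans(ref)) * 1.05, 2, colMeans(ref), "+")
  anchor <- data.frame(element = 1L, r = 0.3, s = -0.4)
  mesh <- list(elements = matrix(1:4, 1), n = 2, m = 2)
  N <- shape_functions(anchor$r, anchor$s)
  h0 <- as.numeric(N %*% ref)
  ht <- as.numeric(N %*% cur)
  expect_equal(ht, colMeans(ref) + 1.05 * (h0 - colMeans(ref)),
               tolerance = 1e-12)

  ## a corner anchor follows that node's trajectory exactly
  ca <- hg$per_seg[[1]]$anchor[1, ]
  ca$r <- -1; ca$s <- -1
  trc <- track_homogeneous_point(ca, g, hg$per_seg[[1]]$mesh)
  node1 <- hg$per_seg[[1]]$mesh$elements[ca$element, 1]
  expect_equal(trc[2, 1, ], frame_nodes(g, 2)[node1, ], tolerance = 1e-12)
})

test_that("model averaging is the exact arithmetic mean", {
  ax <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  g <- tube_grid(n = 6, m = 36, radius = 10, len = 40, frames = 3)
  hg <- make_homogeneous_grid(list(g, g), ax, n_H = 4)
  tr <- track_homogeneous_point(hg$per_seg[[1]]$anchor, g, hg$per_seg[[1]]$mesh)
  ## identical inputs: the average equals any input
  avg <- average_models(list(tr, tr, tr), hg)
  expect_equal(dim(avg$positions), c(3L, 4L, 36L, 3L))
  flat <- aperm(avg$positions, c(1, 3, 2, 4))
  ## displaced copy: midpoint recovered
  d <- c(2, 0, -1)
  tr2 <- tr
  for (k in 1:3) tr2[, , k] <- tr2[, , k] + d[k]
  avg2 <- average_models(list(tr, tr2), hg)
  tr_mid <- track_homogeneous_point(hg$per_seg[[1]]$anchor, g,
                                    hg$per_seg[[1]]$mesh)
  for (k in 1:3) tr_mid[, , k] <- tr_mid[, , k] + d[k] / 2
  got <- sapply(1:3, function(k) as.numeric(t(avg2$positions[2, , , k])))
  expect_equal(got, matrix(tr_mid[2, , ], ncol = 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## shape mismatches are rejected
  expect_error(average_models(list(tr, tr[, 1:10, ]), hg), "shape")
})

test_that("tracked points stay inside convex host elements in every frame", {
  truth <- generate_phantom(phantom_spec(n = 10, frames = 6))
  segs <- make_segmentations(truth, K = 2, sigma_n = 0, seed = 3)
  avg <- average_segmentations(segs)
  ## every averaged node must lie within the bounding box of its host
  ## element's nodes (sufficient for the convex-hull property on boxes)
  hg <- avg$hg
  for (k in 1:2) {
    a <- hg$per_seg[[k]]$anchor
    mesh <- hg$per_seg[[k]]$mesh
    for (t in c(1, 4)) {
      nodes <- frame_nodes(segs[[k]], t)
      tr <- track_homogeneous_point(a, segs[[k]], mesh)
      for (kk in 1:3) {
        corners <- matrix(nodes[mesh$elements[a$element, ], kk], ncol = 4)
        expect_true(all(tr[t, , kk] >= apply(corners, 1, min) - 1e-9))
        expect_true(all(tr[t, , kk] <= apply(corners, 1, max) + 1e-9))
      }
    }
  }
})
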