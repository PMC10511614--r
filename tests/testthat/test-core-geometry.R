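test_that("motion grid tables round-trip and validate completeness", {
  g <- tube_grid(n = 3, m = 36, frames = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_motion_grid(g, path)
  g2 <- read_motion_grid(path)
  expect_identical(dim(g2$positions), dim(g$positions))
  expect_identical(g2$positions, g$positions)   # bit-identical round trip

  ## a full 36 x 36 export (1296 points per frame) parses with n = 36
  g36 <- tube_grid(n = 36, m = 36, frames = 2)
  p36 <- withr::local_tempfile(fileext = ".csv")
  write_motion_grid(g36, p36)
  expect_equal(n_heights(read_motion_grid(p36)), 36)

  ## a missing cell is a hard error naming the first absent triple
  tab <- read.csv(path)
  tab <- tab[!(tab$frame == 1 & tab$i == 0 & tab$j == 5), ]
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, bad, row.names = FALSE)
  expect_error(read_motion_grid(bad), "\\(1,0,5\\)")

  ## non-finite coordinates are rejected
  tab2 <- read.csv(path)
  tab2$x[3] <- NA
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab2, bad2, row.names = FALSE)
  expect_error(read_motion_grid(bad2), "non-finite")
})

test_that("pseudo-apex trimming keeps contiguous interior heights", {
  g <- tube_grid(n = 36, m = 36, frames = 2)
  expect_equal(n_heights(trim_pseudo_apex(g, 1:14)), 22)
  expect_identical(trim_pseudo_apex(g, integer(0)), g)
  ## trimming 22 cap rows leaves 14 heights -> 468 elements, 504 nodes
  g14 <- trim_pseudo_apex(g, 1:22)
  expect_equal(n_heights(g14), 14)
  mesh <- build_quad_mesh(g14)
  expect_equal(nrow(mesh$elements), 13 * 36)
  expect_equal(g14$positions |> dim() |> (\(d) d[2] * d[3])(), 504)
  ## interior drops would break connectivity
  expect_error(trim_pseudo_apex(g, c(1, 3)), "contiguous")
  expect_error(trim_pseudo_apex(g, 2:35), "contiguous")  # interior run
  expect_equal(n_heights(trim_pseudo_apex(g, c(1:3, 30:36))), 26)
  expect_error(trim_pseudo_apex(g, 1:35), "fewer than 2")
})

test_that("quad meshes are circumferentially closed with consistent wrap", {
  g <- tube_grid(n = 2, m = 36)
  mesh <- build_quad_mesh(g)
  expect_equal(nrow(mesh$elements), 36)
  ## the wrap element (i = 1, j = 36) connects back to column 1
  wrap <- mesh$elements[mesh$el_ij[, "i"] == 1 & mesh$el_ij[, "j"] == 36, ]
  nid <- function(i, j) (i - 1) * 36 + j
  expect_equal(as.integer(wrap), c(nid(1, 36), nid(1, 1), nid(2, 1), nid(2, 36)))
  expect_true(all(apply(mesh$elements, 1, \(e) length(unique(e)) == 4)))
  g14 <- tube_grid(n = 14, m = 36)
  expect_equal(nrow(build_quad_mesh(g14)$elements), 468)
})

test_that("summed element areas approach the analytic cylinder area", {
  rho <- 12; len <- 50
  areas <- sapply(c(8, 16, 32), function(n) {
    g <- tube_grid(n = n, m = 36, radius = rho, len = len)
    mesh_area(build_quad_mesh(g), frame_nodes(g, 1))
  })
  exact <- 2 * pi * rho * len
  ## chord approximation: area deficit is sin(pi/m)/(pi/m) in m, fixed here,
  ## so compare against the chord-corrected value and require convergence
  chord <- exact * sin(pi / 36) / (pi / 36)
  expect_lt(abs(areas[3] - chord) / chord, 1e-10)
  expect_true(all(abs(areas - exact) / exact < 0.005))
})

test_that("axis fitting is deterministic, equivariant and noise-tolerant", {
  g <- tube_grid(n = 8, m = 36, radius = 8, len = 60)
  ax <- fit_axis(frame_nodes(g, 1))
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-12)
  ## rigidly rotated cloud: axis rotates identically (up to sign convention)
  set.seed(42)
  R <- random_rotation()
  ax2 <- fit_axis(frame_nodes(g, 1) %*% t(R))
  target <- as.numeric(R %*% ax$direction)
  expect_equal(abs(sum(ax2$direction * target)), 1, tolerance = 1e-12)
  ## noisy cylinder: axis within 1 degree over seeded replicates
  set.seed(7)
  for (rep in 1:5) {
    pts <- frame_nodes(g, 1) + matrix(rnorm(length(frame_nodes(g, 1)),
                                            sd = 0.1), ncol = 3)
    axn <- fit_axis(pts)
    ang <- acos(min(1, abs(sum(axn$direction * c(0, 0, 1))))) * 180 / pi
    expect_lt(ang, 1)
  }
  expect_error(fit_axis(matrix(1, 5, 3)), "degenerate")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_axis(line), "collinear")
})

test_that("cylindrical transform round-trips and honours conventions", {
  ax <- list(origin = c(0, 0, 0), direction = c(1, 0, 0))
  ## point on the axis: R = 0, phi = 0 by convention
  cyl <- to_cylindrical(c(5, 0, 0), ax)
  expect_equal(cyl$R, 0)
  expect_equal(cyl$phi, 0)
  ## 3-4-5 triangle about the x axis
  expect_equal(to_cylindrical(c(0, 3, 4), ax)$R, 5)
  ## round trip within 1e-12 mm for arbitrary axes
  set.seed(11)
  for (rep in 1:5) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    axr <- list(origin = rnorm(3), direction = d)
    pts <- matrix(rnorm(60, sd = 20), ncol = 3)
    back <- from_cylindrical(to_cylindrical(pts, axr), axr)
    expect_lt(max(abs(back - pts)), 1e-12)
  }
})

test_that("point clouds round-trip through XYZ and ASCII PLY", {
  set.seed(33)
  pc <- point_cloud(matrix(rnorm(90, sd = 20), ncol = 3), "wall")
  fx <- withr::local_tempfile(fileext = ".xyz")
  write_point_cloud(pc, fx)
  back <- read_point_cloud(fx)
  expect_equal(unclass(back), unclass(pc), ignore_attr = TRUE)
  fp <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(pc, fp)
  backp <- read_point_cloud(fp, label = "calcification")
  expect_equal(unclass(backp), unclass(pc), ignore_attr = TRUE)
  expect_identical(attr(backp, "label"), "calcification")
  ## commented XYZ lines and comma separators are tolerated
  writeLines(c("# header", "1, 2, 3", "4 5 6"), fx)
  expect_equal(nrow(read_point_cloud(fx)), 2)
})
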