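test_that("coverage fractions count captured lattice samples", {
  ## one planar rectangular element, 4 x 2 mm, in the z = 0 plane
  nodes <- embed_element(unit_element(4, 2))
  mesh <- list(elements = matrix(1:4, 1), n = 2, m = 1,
               el_ij = cbind(i = 1L, j = 1L))
  ## no calcification points -> 0
  expect_equal(coverage_fraction(mesh, nodes, NULL), 0)
  ## dense cover of the whole element -> 1
  gg <- as.matrix(expand.grid(x = seq(0, 4, 0.1), y = seq(0, 2, 0.1), z = 0))
  expect_equal(coverage_fraction(mesh, nodes, point_cloud(gg, "calcification"),
                                 capture_radius = 0.2), 1)
  ## patch covering exactly the circumferential s... (here: y > 1 half)
  half <- gg[gg[, 2] > 1, ]
  cov <- coverage_fraction(mesh, nodes, point_cloud(half, "calcification"),
                           capture_radius = 0.11)
  expect_gte(cov, 0.45)
  expect_lte(cov, 0.55)
})

test_that("element classification applies the half-area rule and patch filter", {
  truth <- generate_phantom(phantom_spec(n = 8, frames = 3))
  mesh <- truth$mesh
  nodes <- frame_nodes(truth$grid, 1)
  ## coverage below one half is non-calcified: thin strip over one edge
  el <- mesh$elements[1, ]
  quad <- nodes[el, ]
  strip <- quad[1, , drop = FALSE]   # a single corner point, tiny coverage
  lab <- classify_elements(mesh, nodes, point_cloud(strip, "calcification"),
                           capture_radius = 0.5)
  expect_false(lab$calcified[1])
  expect_lt(lab$coverage[1], 0.5)
  ## full cover of one element: calcified at min_patch_elements = 1 ...
  dense <- t(sapply(seq_len(200), function(i) {
    w <- as.numeric(shape_functions(runif(1, -1, 1), runif(1, -1, 1)))
    colSums(w * quad)
  }))
  lab1 <- classify_elements(mesh, nodes, point_cloud(dense, "calcification"),
                            capture_radius = 0.6, min_patch_elements = 1)
  expect_true(lab1$calcified[1])
  ## ... but cleared when a minimum patch of 2 elements is required
  lab2 <- classify_elements(mesh, nodes, point_cloud(dense, "calcification"),
                            capture_radius = 0.6, min_patch_elements = 2)
  expect_false(any(lab2$calcified))
  ## classification is invariant to calcification point order
  perm <- sample(nrow(dense))
  lab3 <- classify_elements(mesh, nodes,
                            point_cloud(dense[perm, ], "calcification"),
                            capture_radius = 0.6)
  expect_identical(lab3$calcified, lab1$calcified)
  expect_equal(lab3$coverage, lab1$coverage)
})

test_that("distribution indices reproduce hand arithmetic and scale correctly", {
  amps <- data.frame(element = 1:6,
                     amp11 = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
                     amp22 = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.05),
                     degenerate = FALSE)
  labels <- data.frame(element = 1:6, coverage = 0,
                       calcified = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  di <- distribution_indices(amps, labels)
  row <- di[di$component == "eps22" & di$region == "calcified", ]
  ## {1,2,3,4} %: mean 2.5, max 4, ratio 1.6, heterogeneity 0.5164 (sd 1.2910)
  expect_equal(row$mean_pct, 2.5)
  expect_equal(row$max_pct, 4)
  expect_equal(row$strain_ratio, 1.6)
  expect_equal(row$heterogeneity, 0.5163978, tolerance = 1e-6)
  expect_equal(row$median_pct, 2.5)
  ## constant amplitudes: ratio 1, heterogeneity 0
  rowc <- di[di$component == "eps11" & di$region == "calcified", ]
  expect_equal(rowc$strain_ratio, 1)
  expect_equal(rowc$heterogeneity, 0)
  ## single-element region: ratio 1, heterogeneity undefined (NA, not Inf)
  lab1 <- data.frame(element = 1:6, coverage = 0,
                     calcified = c(TRUE, rep(FALSE, 5)))
  di1 <- distribution_indices(amps, lab1)
  r1 <- di1[di1$component == "eps22" & di1$region == "calcified", ]
  expect_equal(r1$strain_ratio, 1)
  expect_true(is.na(r1$heterogeneity))
  ## scale equivariance: c * amplitudes scales mean/max, fixes ratio and CV
  amps2 <- amps
  amps2$amp22 <- amps$amp22 * 3.7
  di2 <- distribution_indices(amps2, labels)
  r2 <- di2[di2$component == "eps22" & di2$region == "calcified", ]
  expect_equal(r2$mean_pct, row$mean_pct * 3.7)
  expect_equal(r2$max_pct, row$max_pct * 3.7)
  expect_equal(r2$strain_ratio, row$strain_ratio)
  expect_equal(r2$heterogeneity, row$heterogeneity)
  ## degenerate elements are excluded
  amps3 <- amps
  amps3$degenerate[4] <- TRUE
  di3 <- distribution_indices(amps3, labels)
  r3 <- di3[di3$component == "eps22" & di3$region == "calcified", ]
  expect_equal(r3$n, 3)
  expect_equal(r3$max_pct, 3)
})

test_that("left-tail Mann-Whitney matches exact enumeration", {
  res <- mannwhitney_left(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.05)          # = 1/20, fully separated groups
  expect_equal(res$p_value, mw_left_exact(c(1, 2, 3), c(4, 5, 6)))
  expect_identical(res$method, "exact")
  expect_identical(res$stars, "")
  ## reversed separation: left-tail p = 1
  expect_equal(mannwhitney_left(c(4, 5, 6), c(1, 2, 3))$p_value, 1)
  ## random small samples agree with the enumeration oracle
  set.seed(14)
  for (rep in 1:10) {
    x <- round(rnorm(4), 4); y <- round(rnorm(5) + 0.5, 4)
    expect_equal(mannwhitney_left(x, y)$p_value, mw_left_exact(x, y),
                 tolerance = 1e-12)
  }
  ## larger samples switch to the corrected normal approximation
  set.seed(15)
  big <- mannwhitney_left(rnorm(30), rnorm(40))
  expect_identical(big$method, "normal approximation")
  expect_error(mannwhitney_left(numeric(0), 1:3), "at least one")
})

test_that("KS normality check flags heavy non-normality only", {
  set.seed(16)
  notrej <- sum(vapply(1:20, function(i) ks_normality(rnorm(300))$normal,
                       logical(1)))
  expect_gte(notrej, 18)                    # >= 90% not rejected
  expect_false(ks_normality(exp(rnorm(500)))$normal)
  expect_error(ks_normality(rnorm(4)), "at least 5")
})
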