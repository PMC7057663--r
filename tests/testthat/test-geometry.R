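test_that("quadrature lattice covers units and assignments are disjoint", {
  u <- area_units("A", "coarse", list(rect_ring(0, 1000, 0, 1000)))
  g <- build_quadrature_grid(u, 500, quiet = TRUE)
  expect_equal(nrow(g$points), 4L)
  expect_true(all(g$part_index$coarse == 1L))

  u2 <- area_units(c("A", "B"), "coarse",
                   list(rect_ring(0, 1000, 0, 1000), rect_ring(2000, 3000, 0, 1000)))
  g2 <- build_quadrature_grid(u2, 500, quiet = TRUE)
  ia <- which(g2$part_index$coarse == 1L)
  ib <- which(g2$part_index$coarse == 2L)
  expect_length(intersect(ia, ib), 0)
  expect_true(length(ia) == 4L && length(ib) == 4L)
})

test_that("a unit missed by the lattice errors or gets a centroid node", {
  u <- area_units(c("big", "tiny"), "coarse",
                  list(rect_ring(0, 2000, 0, 2000), rect_ring(2050, 2120, 0, 70)))
  expect_error(build_quadrature_grid(u, 500, quiet = TRUE), "tiny")
  g <- build_quadrature_grid(u, 500, quiet = TRUE, on_empty = "centroid")
  expect_gte(sum(g$part_index$coarse == 2L, na.rm = TRUE), 1L)
  extra <- g$points[which(g$part_index$coarse == 2L), , drop = FALSE]
  expect_true(all(points_in_polygon(extra, u$geometry[[2]])))
})

test_that("voronoi tessellation tiles the domain and every cell gets points", {
  units <- make_misaligned_partitions(c(0, 10000, 0, 10000), 20, 20,
                                      style = "voronoi", seed = 7)
  coarse <- units[units$partition == "coarse", ]
  expect_equal(sum(coarse$area), 1e8, tolerance = 1e-9)
  g <- build_quadrature_grid(coarse, 250, quiet = TRUE)
  expect_equal(nrow(g$points), 40L * 40L)
  counts <- tabulate(g$part_index$coarse, nbins = 20)
  expect_true(all(counts >= 1L))
  # brute-force cross-check: each point is inside exactly one cell
  n_in <- rowSums(vapply(coarse$geometry,
                         function(gm) points_in_polygon(g$points, gm),
                         logical(nrow(g$points))))
  expect_true(all(n_in == 1L))
})

test_that("areal correlation factor has closed forms in the point limit", {
  # two 1 km squares whose single quadrature points are 2000 m apart
  u <- area_units(c("A", "B"), "coarse",
                  list(rect_ring(0, 1000, 0, 1000), rect_ring(2000, 3000, 0, 1000)))
  g <- build_quadrature_grid(u, 1000, quiet = TRUE)
  expect_equal(areal_correlation_factor(g, "A", "A", delta = 500), 1.0)
  expect_equal(areal_correlation_factor(g, "A", "B", delta = 2000), exp(-1))
  expect_identical(areal_correlation_factor(g, "A", "B", delta = 700),
                   areal_correlation_factor(g, "B", "A", delta = 700))
  expect_error(areal_correlation_factor(g, "A", "B", delta = -1), "delta")
})

test_that("quadrature refinement converges and is within 1% by 50 m", {
  u <- area_units(c("A", "B"), "coarse",
                  list(rect_ring(0, 1000, 0, 1000), rect_ring(5000, 6000, 0, 1000)))
  f <- vapply(c(200, 100, 50), function(s) {
    g <- build_quadrature_grid(u, s, quiet = TRUE)
    areal_correlation_factor(g, "A", "B", delta = 1533)
  }, 0)
  expect_gte(abs(f[1] - f[2]), abs(f[2] - f[3]))
  g250 <- build_quadrature_grid(u, 250, quiet = TRUE)
  f250 <- areal_correlation_factor(g250, "A", "B", delta = 1533)
  expect_equal(f250, f[3], tolerance = 0.01)
})

test_that("areal covariance reduces to the pointwise kernel for point units", {
  set.seed(4)
  cells <- cbind(sample(1:15, 5), sample(1:15, 5))
  units <- degenerate_point_units(cells, cbind(sample(1:15, 4), sample(1:15, 4)))
  g <- build_quadrature_grid(units, 100, quiet = TRUE)
  centres <- (cells - 0.5) * 100
  S <- areal_cov_matrix(g, tau2 = 2.5, delta = 700, partition = "coarse")
  expect_equal(unname(S), exp_cov(pair_dist(centres, centres), 2.5, 700),
               tolerance = 1e-12)
})

test_that("areal covariance matches Monte-Carlo covariances of unit averages", {
  units <- square_partitions(n_coarse = 5, n_fine = 9, size = 2000)
  coarse <- units[units$partition == "coarse", ]
  g <- build_quadrature_grid(coarse, 200, quiet = TRUE)
  S <- areal_cov_matrix(g, tau2 = 1, delta = 1000, partition = "coarse")
  expect_true(all(diag(S) <= 1 + 1e-12))

  B <- 10000
  draws <- simulate_gp(g$points, tau2 = 1, delta = 1000, n_draws = B, seed = 99)
  grp <- g$part_index$coarse
  ubar <- t(rowsum(t(draws), grp)) / rep(tabulate(grp), each = B)
  S_hat <- stats::cov(ubar)
  se <- sqrt((outer(diag(S), diag(S)) + S^2) / B)
  expect_true(all(abs(S_hat - S) <= 3 * se))
})

test_that("point-to-areal covariance interpolates the kernel", {
  u <- area_units(c("A", "B"), "coarse",
                  list(rect_ring(0, 1000, 0, 1000), rect_ring(2000, 3000, 0, 1000)))
  g <- build_quadrature_grid(u, 1000, quiet = TRUE)
  expect_equal(point_to_areal_cov(c(500, 500), g, "A", tau2 = 3, delta = 800), 3)
  expect_equal(point_to_areal_cov(c(500, 2500), g, "A", tau2 = 3, delta = 1000),
               3 * exp(-2))
  # dense-grid oracle for a real areal integral
  x <- c(2500, 500)
  v <- vapply(c(250, 50), function(s) {
    gs <- build_quadrature_grid(u, s, quiet = TRUE)
    point_to_areal_cov(x, gs, "A", tau2 = 1, delta = 1533)
  }, 0)
  expect_equal(v[1], v[2], tolerance = 0.01)
})

test_that("histogram-accelerated factors agree with exact quadrature", {
  fx <- small_fixture(seed = 3, spacing = 250, sim_spacing = 250)
  g <- fx$grid
  for (delta in c(400, 1500, 4000)) {
    Fe <- arealgp:::kernel_factors(g, delta)
    Ff <- arealgp:::kernel_factors_fast(g, delta)
    for (blk in c("cc", "ff", "cf")) {
      expect_lt(max(abs(Fe[[blk]] - Ff[[blk]])), 5e-3)
    }
  }
})

test_that("grid export writes coordinates with unit assignments", {
  units <- square_partitions(n_coarse = 4, n_fine = 4, size = 1000)
  g <- build_quadrature_grid(units, 250, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- export_grid(g, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(g$points))
  expect_true(all(c("x", "y", "coarse_id", "fine_id") %in% names(back)))
})
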