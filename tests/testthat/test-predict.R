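test_that("without an association the predicted surface is flat at alpha", {
  fx <- small_fixture(seed = 3)
  p0 <- model_params(alpha = c(74, 80), beta = c(0, 0), gamma = 40,
                     tau2 = 300, delta = 1000, nu2 = 10, omega = c(6, 13, 5))
  fit <- plugin_fit(p0, fx$data, fx$grid, variant = "full")
  lat <- prediction_lattice(fx$scenario$units, spacing = 500)
  pf <- predictive_distribution(fit, lat)
  expect_equal(pf$mean[, 1], rep(74, nrow(lat)), tolerance = 1e-8)
  expect_equal(pf$mean[, 2], rep(80, nrow(lat)), tolerance = 1e-8)
  expect_equal(max(pf$sd), 0, tolerance = 1e-6)
})

test_that("prediction at a near-point unit recovers the de-noised observation", {
  # coarse units collapse to single lattice points; tiny noise means the
  # observation pins the latent surface at that point
  units <- degenerate_point_units(cbind(c(2, 6, 10), c(2, 5, 8)),
                                  cbind(c(3, 8, 11), c(9, 3, 10)))
  g <- build_quadrature_grid(units, 100, quiet = TRUE)
  p <- model_params(alpha = c(75, 81), beta = c(1, 0.5), gamma = 40,
                    tau2 = 25, delta = 600, nu2 = 4,
                    omega = c(1e-4, 1e-4, 0))
  data <- misaligned_data(
    units,
    outcome = data.frame(id = c("c01", "c02", "c03"),
                         leb1 = c(73, 76, 78), leb2 = c(80, 81.5, 82)),
    covariate = data.frame(id = c("f01", "f02", "f03"), imd = c(45, 38, 30))
  )
  fit <- plugin_fit(p, data, g, variant = "full")
  x0 <- matrix(c(150, 150), 1)  # the first coarse unit's only point
  pf <- predictive_distribution(fit, x0)
  expect_equal(pf$mean[1, 1], 73, tolerance = 0.01)
  expect_lt(pf$sd[1, 1]^2, 0.05 * p$beta[1]^2 * p$tau2)
})

test_that("conditioning never inflates the predictive variance", {
  fx <- small_fixture(seed = 6)
  fit <- plugin_fit(fx$params, fx$data, fx$grid)
  lat <- prediction_lattice(fx$scenario$units, spacing = 400)
  for (cond in c("all_data", "leb_only")) {
    pf <- predictive_distribution(fit, lat, conditioning = cond)
    prior <- rep(fit$params_hat$beta^2 * fit$params_hat$tau2, each = nrow(lat))
    expect_true(all(c(pf$sd^2) <= prior + 1e-8))
  }
})

test_that("predictive sampling is seeded, reproducible and moment-consistent", {
  fx <- small_fixture(seed = 7)
  fit <- plugin_fit(fx$params, fx$data, fx$grid)
  lat <- prediction_lattice(fx$scenario$units, spacing = 800)
  pf <- predictive_distribution(fit, lat, keep_cov = TRUE)

  s1 <- sample_predictive(pf, n_draws = 1, seed = 31)
  s2 <- sample_predictive(pf, n_draws = 1, seed = 31)
  expect_identical(s1$samples, s2$samples)

  sm <- sample_predictive(pf, n_draws = 10000, seed = 5)
  mc_se <- sqrt(diag(pf$cov)) / sqrt(10000)
  expect_true(all(abs(colMeans(sm$samples) - c(pf$mean)) <= 3 * mc_se + 1e-9))

  zero <- pf
  zero$cov <- matrix(0, nrow(pf$cov), ncol(pf$cov))
  zs <- sample_predictive(zero, n_draws = 3, seed = 1)
  expect_equal(zs$samples, matrix(rep(c(pf$mean), each = 3), nrow = 3),
               ignore_attr = TRUE)
})

test_that("non-exceedance probabilities are closed-form Gaussian tails", {
  fx <- small_fixture(seed = 7)
  fit <- plugin_fit(fx$params, fx$data, fx$grid)
  lat <- prediction_lattice(fx$scenario$units, spacing = 800)
  pf <- predictive_distribution(fit, lat, keep_cov = TRUE)

  expect_equal(nep(pf, 1, 1e6), rep(1, nrow(lat)))
  l_mid <- pf$mean[3, 1]
  expect_equal(nep(pf, 1, l_mid)[3], 0.5)
  n1 <- nep(pf, 1, 75); n2 <- nep(pf, 1, 78)
  expect_true(all(n2 >= n1))

  # agreement with the sampling estimate
  sm <- sample_predictive(pf, n_draws = 10000, seed = 9)
  l <- 76
  frac <- colMeans(sm$samples[, seq_len(nrow(lat)), drop = FALSE] < l)
  p_cl <- nep(pf, 1, l)
  mc_se <- sqrt(pmax(p_cl * (1 - p_cl), 1e-4) / 10000)
  expect_true(all(abs(frac - p_cl) <= 4 * mc_se))
})

test_that("nep classification uses the stated cut-offs", {
  v <- c(0.95, 0.5, 0.05, 0.8, 0.2)
  lab <- classify_nep(v)
  expect_equal(as.character(lab),
               c("likely_below", "uncertain", "likely_above",
                 "likely_below", "likely_above"))
  expect_error(classify_nep(v, low = 0.9, high = 0.2), "low")
})

test_that("areal predictions aggregate the continuous surface consistently", {
  fx <- small_fixture(seed = 12)
  fit <- plugin_fit(fx$params, fx$data, fx$grid)
  ap <- areal_prediction(fit)
  expect_true(all(ap$sd >= 0))
  expect_true(all(ap$lower <= ap$mean & ap$mean <= ap$upper))

  # averaging continuous predictions over a unit's quadrature points must
  # reproduce the unit's areal predictive mean
  g <- fx$grid
  j <- 2L
  pts_j <- g$points[which(g$part_index$coarse == j), , drop = FALSE]
  pf <- predictive_distribution(fit, pts_j, keep_cov = FALSE)
  expect_equal(mean(pf$mean[, 1]), ap$mean[ap$group == 1][j], tolerance = 1e-6)
  expect_equal(mean(pf$mean[, 2]), ap$mean[ap$group == 2][j], tolerance = 1e-6)

  # intervals collapse as the outcome noise vanishes
  p_small <- fx$params
  p_small$omega <- diag(c(1e-6, 1e-6))
  fit_small <- plugin_fit(p_small, fx$data, fx$grid, variant = "full")
  ap_small <- areal_prediction(fit_small)
  expect_lt(median(ap_small$sd), median(ap$sd))
})

test_that("surface export and contours round-trip through CSV", {
  fx <- small_fixture(seed = 13)
  fit <- plugin_fit(fx$params, fx$data, fx$grid)
  lat <- prediction_lattice(fx$scenario$units, spacing = 400)
  pf <- predictive_distribution(fit, lat, keep_cov = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_surface(pf, path, thresholds = c(79.2, 82.9))
  back <- read_surface(path)
  expect_equal(as.data.frame(back), as.data.frame(out), tolerance = 1e-12)
  expect_true(all(back$nep1 >= 0 & back$nep1 <= 1))

  ct <- surface_contours(pf, levels = stats::median(pf$mean[, 1]), group = 1)
  expect_true(all(c("level", "piece", "x", "y") %in% names(ct)))
})
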