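test_that("exponential kernel has its closed-form properties", {
  expect_equal(exp_cov(0, 1, 1), 1)
  expect_equal(exp_cov(2000, 1, 2000), exp(-1))
  d <- c(10, 500, 3000)
  expect_equal(exp_cov(d, 2, 700), exp_cov(2 * d, 2, 1400))
  expect_error(exp_cov(-1, 1, 1), "non-negative")
})

test_that("parameter container validates its invariants", {
  expect_error(model_params(c(1, 2), c(0, 0), 0, tau2 = -1, delta = 1, nu2 = 1,
                            omega = c(1, 1, 0)), "positive")
  expect_error(model_params(c(1, 2), c(0, 0), 0, tau2 = 1, delta = 1, nu2 = 1,
                            omega = c(1, 1, 1.2)), "positive definite")
  p <- liverpool_params()
  th <- arealgp:::params_to_th(p)
  p2 <- arealgp:::th_to_params(th)
  expect_equal(p2$omega, p$omega, tolerance = 1e-12)
  expect_equal(p2$delta, p$delta, tolerance = 1e-12)
})

test_that("joint covariance decouples when beta is zero", {
  fx <- small_fixture(seed = 2)
  p0 <- model_params(alpha = c(75, 81), beta = c(0, 0), gamma = 40,
                     tau2 = 300, delta = 1000, nu2 = 10, omega = c(6, 13, 5))
  S <- build_joint_covariance(p0, fx$data, fx$grid)
  n <- length(fx$data$coarse_ids); m <- length(fx$data$fine_ids)
  expect_equal(S[seq_len(2 * n), 2 * n + seq_len(m)],
               matrix(0, 2 * n, m), ignore_attr = TRUE)
  expect_equal(S[seq_len(n), seq_len(n)], diag(6, n), ignore_attr = TRUE)
  expect_equal(S[seq_len(n), n + seq_len(n)], diag(5, n), ignore_attr = TRUE)
})

test_that("likelihood matches a hand-assembled trivariate normal", {
  skip_if_not_installed("mvtnorm")
  # one coarse and one fine unit, both collapsing to single points
  units <- degenerate_point_units(cbind(2, 2), cbind(5, 2))
  g <- build_quadrature_grid(units, 100, quiet = TRUE)
  data <- misaligned_data(
    units, outcome = data.frame(id = "c01", leb1 = 74.2, leb2 = 80.1),
    covariate = data.frame(id = "f01", imd = 42)
  )
  p <- model_params(alpha = c(75, 81), beta = c(-0.2, -0.1), gamma = 40,
                    tau2 = 100, delta = 500, nu2 = 9, omega = c(4, 9, 2))
  d <- 300  # distance between the two cell centres
  k <- exp_cov(d, p$tau2, p$delta)
  S <- rbind(
    c(p$beta[1]^2 * p$tau2 + 4, p$beta[1] * p$beta[2] * p$tau2 + 2, p$beta[1] * k),
    c(p$beta[1] * p$beta[2] * p$tau2 + 2, p$beta[2]^2 * p$tau2 + 9, p$beta[2] * k),
    c(p$beta[1] * k, p$beta[2] * k, p$tau2 + 9)
  )
  oracle <- mvtnorm::dmvnorm(c(74.2, 80.1, 42), mean = c(75, 81, 40),
                             sigma = S, log = TRUE)
  expect_equal(log_likelihood(p, data, g), oracle, tolerance = 1e-7)
  expect_equal(log_likelihood(p, data, g, method = "joint"), oracle,
               tolerance = 1e-7)
})

test_that("factorized and stacked likelihoods agree on random instances", {
  set.seed(42)
  for (i in 1:6) {
    fx <- small_fixture(seed = i, n_coarse = 4, n_fine = 8, size = 3000,
                        spacing = 300, sim_spacing = 300,
                        params = random_params())
    p <- random_params()
    ll_f <- log_likelihood(p, fx$data, fx$grid)
    ll_j <- log_likelihood(p, fx$data, fx$grid, method = "joint")
    expect_equal(ll_f, ll_j, tolerance = 1e-6)
  }
})

test_that("with beta zero the likelihood separates into outcome and covariate terms", {
  skip_if_not_installed("mvtnorm")
  fx <- small_fixture(seed = 5)
  p0 <- model_params(alpha = c(75, 81), beta = c(0, 0), gamma = 40,
                     tau2 = 300, delta = 1000, nu2 = 10, omega = c(6, 13, 5))
  n <- length(fx$data$coarse_ids); m <- length(fx$data$fine_ids)
  In <- diag(n)
  S_leb <- rbind(cbind(6 * In, 5 * In), cbind(5 * In, 13 * In))
  ll_leb <- mvtnorm::dmvnorm(c(fx$data$outcome), mean = rep(c(75, 81), each = n),
                             sigma = S_leb, log = TRUE)
  S_imd <- areal_cov_matrix(fx$grid, 300, 1000, "fine") + 10 * diag(m)
  ll_imd <- mvtnorm::dmvnorm(fx$data$covariate, mean = rep(40, m),
                             sigma = S_imd, log = TRUE)
  expect_equal(log_likelihood(p0, fx$data, fx$grid), ll_leb + ll_imd,
               tolerance = 1e-6)
})

test_that("maximum-likelihood fit satisfies nesting, fixed-point and shift invariance", {
  fx <- small_fixture(seed = 8, n_coarse = 8, n_fine = 16, size = 5000,
                      spacing = 250, sim_spacing = 250)
  fit <- suppressWarnings(fit_mle(fx$data, fx$grid, n_starts = 2,
                                  control = list(maxit = 200)))
  expect_true(is.finite(fit$loglik))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 11L)
  expect_true(all(is.finite(tidy(fit)$std.error)))

  reduced <- suppressWarnings(fit_mle(fx$data, fx$grid, variant = "no_covariate",
                                      n_starts = 2, control = list(maxit = 200)))
  expect_gte(fit$loglik, reduced$loglik - 1e-6)
  expect_equal(nrow(tidy(reduced)), 9L)

  refit <- suppressWarnings(fit_mle(fx$data, fx$grid, init = fit$params_hat,
                                    n_starts = 1, control = list(hessian = FALSE)))
  expect_lt(abs(refit$loglik - fit$loglik), 1e-4)

  # adding a constant to the covariate shifts gamma and nothing else
  d2 <- fx$data
  d2$covariate <- d2$covariate + 25
  fit2 <- suppressWarnings(fit_mle(d2, fx$grid, init = fit$params_hat,
                                   n_starts = 1, control = list(hessian = FALSE)))
  expect_equal(fit2$params_hat$gamma, fit$params_hat$gamma + 25, tolerance = 0.05)
  expect_equal(fit2$params_hat$beta, fit$params_hat$beta, tolerance = 0.02)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 0.05)
})

test_that("single-replicate recovery lands near the generating parameters", {
  sc <- synthetic_scenario(seed = 2)
  data <- simulate_dataset(sc, seed = 21)
  fit <- suppressWarnings(fit_mle(data, sc$sim_grid,
                                  control = list(maxit = 120, reltol = 1e-8)))
  th_true <- arealgp:::params_to_th(sc$true_params)
  se <- sqrt(diag(fit$vcov))
  z <- abs(fit$th_hat - th_true) / se
  # allow one-in-a-thousand excursions per coordinate
  expect_true(all(z[c("beta1", "beta2", "alpha1", "alpha2", "gamma")] < 4))
})

test_that("closed-form summaries reproduce their definitions", {
  expect_equal(variance_explained(0, 10, 5), 0)
  expect_equal(variance_explained(1, 1, 1), 0.5)
  expect_true(variance_explained(-2, 1, 1) > variance_explained(-1, 1, 1))
  expect_equal(cross_group_correlation(diag(2)), 0)
  eps <- 1e-6
  expect_equal(cross_group_correlation(matrix(c(1, 1 - eps, 1 - eps, 1), 2)),
               1 - eps)
  expect_equal(practical_range(1, 0.05), -log(0.05))
  expect_equal(practical_range(1000, 1), 0)
  expect_error(practical_range(-1), "positive")
})

test_that("likelihood-ratio test is zero for identical fits and calibrated under the null", {
  fx <- small_fixture(seed = 9)
  p0 <- model_params(alpha = c(75, 81), beta = c(0, 0), gamma = 40,
                     tau2 = 300, delta = 1000, nu2 = 10, omega = c(6, 13, 5))
  f_full <- plugin_fit(p0, fx$data, fx$grid, variant = "full")
  f_red <- plugin_fit(p0, fx$data, fx$grid, variant = "no_covariate")
  lrt <- lr_test(f_full, f_red)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$p.value, 1)

  # small null simulation: rejection rate at 5% within wide binomial bounds
  p_null <- model_params(alpha = c(75, 81), beta = c(0, 0), gamma = 40,
                         tau2 = 200, delta = 800, nu2 = 10, omega = c(6, 13, 4))
  sc <- synthetic_scenario(domain = c(0, 4000, 0, 4000), n_coarse = 6,
                           n_fine = 12, style = "grid", sim_grid_spacing = 250,
                           true_params = p_null, seed = 3)
  rejections <- 0L
  set.seed(17)
  n_rep <- 18L
  for (b in seq_len(n_rep)) {
    d <- simulate_dataset(sc, seed = NULL)
    ff <- tryCatch(suppressWarnings(
      fit_mle(d, sc$sim_grid,
              control = list(maxit = 150, reltol = 1e-8, hessian = FALSE))),
      error = function(e) NULL)
    fr <- tryCatch(suppressWarnings(
      fit_mle(d, sc$sim_grid, variant = "no_covariate",
              control = list(maxit = 150, reltol = 1e-8, hessian = FALSE))),
      error = function(e) NULL)
    if (is.null(ff) || is.null(fr)) next
    if (lr_test(ff, fr)$p.value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, qbinom(0.999, n_rep, 0.05) + 1L)

  # power: a strong association is detected decisively
  p_alt <- model_params(alpha = c(75, 81), beta = c(-1.5, -1.2), gamma = 40,
                        tau2 = 200, delta = 800, nu2 = 10, omega = c(2, 3, 1))
  sc2 <- synthetic_scenario(domain = c(0, 4000, 0, 4000), n_coarse = 8,
                            n_fine = 16, style = "grid", sim_grid_spacing = 250,
                            true_params = p_alt, seed = 4)
  for (b in 1:3) {
    d <- simulate_dataset(sc2, seed = 50 + b)
    ff <- suppressWarnings(fit_mle(d, sc2$sim_grid,
                                   control = list(maxit = 200, hessian = FALSE)))
    fr <- suppressWarnings(fit_mle(d, sc2$sim_grid, variant = "no_covariate",
                                   control = list(maxit = 200, hessian = FALSE)))
    expect_lt(lr_test(ff, fr)$p.value, 0.001)
  }
})

test_that("fit report mirrors the two-model tabular layout", {
  fx <- small_fixture(seed = 10)
  f1 <- plugin_fit(fx$params, fx$data, fx$grid, variant = "full")
  f0 <- plugin_fit(liverpool_params("no_covariate"), fx$data, fx$grid,
                   variant = "no_covariate")
  path <- withr::local_tempfile(fileext = ".csv")
  rep <- write_fit_report(f1, f0, path)
  expect_true(file.exists(path))
  expect_true("log_likelihood" %in% rep$term)
  expect_true(all(c("estimate_full", "estimate_no_covariate") %in% names(rep)))
  expect_gte(nrow(rep), 12L)
})
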