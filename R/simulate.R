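#' Simulate a Gaussian process with exponential covariance
#'
#' Draws zero-mean Gaussian surfaces at arbitrary points via dense Cholesky
#' factorization of the covariance matrix (exact, suitable for grids of up
#' to a few thousand points).
#'
#' @param points n x 2 matrix (or data frame) of planar coordinates.
#' @param tau2,delta Kernel parameters.
#' @param n_draws Number of independent draws.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so enclosing simulations stay reproducible from one seed).
#' @param chol_factor Optional precomputed upper Cholesky factor of the
#'   covariance, reused across repeated draws on a fixed point set.
#' @return A numeric vector (one draw) or an `n_draws` x n matrix.
#' @export
simulate_gp <- function(points, tau2, delta, n_draws = 1L, seed = NULL,
                        chol_factor = NULL) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  n <- nrow(pts)
  if (n < 1L) stop("`points` must be non-empty", call. = FALSE)
  if (is.null(chol_factor)) {
    if (n > 8000L) {
      stop("dense factorization of ", n, " points is too large; ",
           "use a coarser simulation grid", call. = FALSE)
    }
    chol_factor <- chol_jitter(exp_cov(pair_dist(pts, pts), tau2, delta))
  }
  draw <- function() {
    Z <- matrix(stats::rnorm(n_draws * n), n_draws, n)
    Z %*% chol_factor
  }
  X <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (n_draws == 1L) drop(X) else X
}

#' Generate two misaligned tessellations of a rectangle
#'
#' Synthetic stand-in for real administrative geographies: a coarse and a
#' fine partition of the same rectangular domain, non-nested by
#' construction for the Voronoi style (independent uniform seeds per
#' partition), or axis-aligned rectangular tilings for the grid style.
#'
#' @param domain Numeric length-4 `c(xmin, xmax, ymin, ymax)` in metres.
#' @param n_coarse,n_fine Cell counts, `n_fine >= n_coarse >= 2`.
#' @param style `"voronoi"` or `"grid"`.
#' @param seed Integer seed.
#' @return Units tibble (see [area_units()]) holding both partitions, ids
#'   `c01, c02, ...` and `f01, f02, ...`.
#' @export
make_misaligned_partitions <- function(domain, n_coarse, n_fine,
                                       style = c("voronoi", "grid"),
                                       seed = 1L) {
  style <- match.arg(style)
  stopifnot(length(domain) == 4L, domain[2L] > domain[1L], domain[4L] > domain[3L])
  if (!(n_fine >= n_coarse && n_coarse >= 2L)) {
    stop("need n_fine >= n_coarse >= 2", call. = FALSE)
  }
  one_partition <- function(n, partition, prefix) {
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    if (style == "voronoi") {
      seeds <- cbind(stats::runif(n, domain[1L], domain[2L]),
                     stats::runif(n, domain[3L], domain[4L]))
      geom <- lapply(seq_len(n), function(i) voronoi_cell(seeds, i, domain))
    } else {
      fac <- grid_factor(n)
      xs <- seq(domain[1L], domain[2L], length.out = fac[1L] + 1L)
      ys <- seq(domain[3L], domain[4L], length.out = fac[2L] + 1L)
      geom <- list()
      for (iy in seq_len(fac[2L])) for (ix in seq_len(fac[1L])) {
        geom[[length(geom) + 1L]] <- rect_ring(xs[ix], xs[ix + 1L], ys[iy], ys[iy + 1L])
      }
    }
    area_units(ids, partition, geom)
  }
  withr::with_seed(seed, dplyr::bind_rows(
    one_partition(n_coarse, "coarse", "c"),
    one_partition(n_fine, "fine", "f")
  ))
}

# Most-square factor pair r x c = n (strips when n is prime).
grid_factor <- function(n) {
  r <- floor(sqrt(n))
  while (n %% r != 0L) r <- r - 1L
  c(as.integer(n / r), as.integer(r))
}

#' Define a synthetic study scenario
#'
#' Bundles everything a simulation needs: a rectangular domain, the two
#' misaligned partitions, the regular simulation grid over which the latent
#' surface is drawn and averaged, and the generating parameters. Defaults
#' emulate a Liverpool-sized study: a 10 km square split into 30 coarse and
#' 90 fine Voronoi cells, a 150 m simulation grid, and the published
#' Liverpool point estimates as true parameters (`delta` is rescaled in
#' proportion to the domain diameter for other domain sizes).
#'
#' @param domain `c(xmin, xmax, ymin, ymax)` in metres.
#' @param n_coarse,n_fine Cell counts.
#' @param style Tessellation style, see [make_misaligned_partitions()].
#' @param sim_grid_spacing Simulation grid spacing in metres (default 150).
#' @param true_params A [model_params()] object, or `NULL` for the default.
#' @param seed Integer seed controlling the tessellation and (by default)
#'   the simulated datasets.
#' @return An object of class `arealgp_scenario`.
#' @export
synthetic_scenario <- function(domain = c(0, 10000, 0, 10000),
                               n_coarse = 30L, n_fine = 90L,
                               style = "voronoi", sim_grid_spacing = 150,
                               true_params = NULL, seed = 1L) {
  units <- make_misaligned_partitions(domain, n_coarse, n_fine, style, seed)
  grid <- build_quadrature_grid(units, sim_grid_spacing, quiet = TRUE,
                                on_empty = "centroid")
  if (is.null(true_params)) {
    ref <- liverpool_params()
    # the default 10 km square is taken as Liverpool-sized; other domains
    # rescale the correlation range with the domain diameter
    diam <- sqrt((domain[2L] - domain[1L])^2 + (domain[4L] - domain[3L])^2)
    true_params <- model_params(
      alpha = ref$alpha, beta = ref$beta, gamma = ref$gamma, tau2 = ref$tau2,
      delta = ref$delta * diam / sqrt(2 * 1e4^2), nu2 = ref$nu2,
      omega = ref$omega
    )
  }
  structure(
    list(domain = domain, units = units, sim_grid = grid,
         true_params = true_params, seed = as.integer(seed),
         cache = new.env(parent = emptyenv())),
    class = "arealgp_scenario"
  )
}

#' @export
print.arealgp_scenario <- function(x, ...) {
  cat("<arealgp_scenario> domain ",
      (x$domain[2L] - x$domain[1L]) / 1000, " x ",
      (x$domain[4L] - x$domain[3L]) / 1000, " km, ",
      sum(x$units$partition == "coarse"), " coarse / ",
      sum(x$units$partition == "fine"), " fine units, sim grid ",
      x$sim_grid$spacing, " m (", nrow(x$sim_grid$points), " points)\n", sep = "")
  invisible(x)
}

scenario_chol <- function(scenario) {
  p <- scenario$true_params
  key <- sprintf("%.17g_%.17g", p$tau2, p$delta)
  if (!identical(scenario$cache$chol_key, key)) {
    S <- exp_cov(grid_dist(scenario$sim_grid), p$tau2, p$delta)
    scenario$cache$chol <- chol_jitter(S)
    scenario$cache$chol_key <- key
  }
  scenario$cache$chol
}

#' Simulate one misaligned dataset from a scenario
#'
#' Draws the latent surface on the simulation grid, averages it over each
#' partition (the per-unit mean of the grid values), and adds the model
#' noise: bivariate `omega` noise on the coarse outcome pairs and `nu2`
#' nugget noise on the fine covariate.
#'
#' @param scenario An [synthetic_scenario()] object.
#' @param seed Integer seed; `NULL` continues the current RNG stream
#'   (used by [coverage_study()] to draw many replicates from one stream).
#' @return A [misaligned_data()] object; the latent truth (grid surface and
#'   unit averages) is attached as attribute `"truth"`.
#' @export
simulate_dataset <- function(scenario, seed = scenario$seed) {
  p <- scenario$true_params
  grid <- scenario$sim_grid
  R <- scenario_chol(scenario)
  gen <- function() {
    U <- simulate_gp(grid$points, p$tau2, p$delta, chol_factor = R)
    idx_c <- !is.na(grid$part_index$coarse)
    idx_f <- !is.na(grid$part_index$fine)
    ubar_c <- rowsum(U[idx_c], grid$part_index$coarse[idx_c])[, 1L] /
      tabulate(grid$part_index$coarse[idx_c])
    ubar_f <- rowsum(U[idx_f], grid$part_index$fine[idx_f])[, 1L] /
      tabulate(grid$part_index$fine[idx_f])
    n <- length(ubar_c); m <- length(ubar_f)
    Tm <- matrix(stats::rnorm(2L * n), n, 2L) %*% chol(p$omega)
    V <- stats::rnorm(m, sd = sqrt(p$nu2))
    list(U = U, ubar_c = ubar_c, ubar_f = ubar_f,
         leb = cbind(p$alpha[1L] + p$beta[1L] * ubar_c + Tm[, 1L],
                     p$alpha[2L] + p$beta[2L] * ubar_c + Tm[, 2L]),
         imd = p$gamma + ubar_f + V)
  }
  sim <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  coarse_ids <- grid_partition_units(grid, "coarse")$id
  fine_ids <- grid_partition_units(grid, "fine")$id
  out <- misaligned_data(
    scenario$units,
    outcome = tibble::tibble(id = coarse_ids, leb1 = sim$leb[, 1L],
                             leb2 = sim$leb[, 2L]),
    covariate = tibble::tibble(id = fine_ids, imd = sim$imd)
  )
  attr(out, "truth") <- list(U = sim$U, ubar_coarse = sim$ubar_c,
                             ubar_fine = sim$ubar_f, params = p)
  out
}

#' Coverage simulation study
#'
#' Repeatedly simulates datasets from a scenario, refits the full model to
#' each, and records whether (a) Wald confidence intervals for `beta1` and
#' `beta2` cover their true values and (b) plug-in prediction intervals
#' cover the true noise-free outcome, both at unit level (`areal`) and at
#' a lattice of point locations (`continuous`), across a ladder of nominal
#' levels. Prediction coverages are averaged over units / lattice points
#' within each replicate. Replicates whose fit fails are logged and
#' excluded.
#'
#' @param scenario An [synthetic_scenario()] object.
#' @param B Number of replicates (at least 50 for a meaningful study).
#' @param levels Nominal coverage levels.
#' @param fit_spacing Quadrature spacing (metres) of the grid used for
#'   fitting; `NULL` (default) reuses the scenario's simulation grid, so
#'   fitting and simulation share one quadrature.
#' @param lattice_stride Keep every `lattice_stride`-th simulation-grid
#'   point (per axis) as the continuous prediction lattice.
#' @param fit_options List passed to the fitting step: `n_starts`
#'   (default 5, run adaptively: extra starts only fire when a fit lands
#'   on the likelihood ridge), `maxit` (default 150), `reltol`
#'   (default 1e-9).
#' @param conditioning Conditioning set for the prediction intervals
#'   (default `"leb_only"`, the conditioning of the printed predictive
#'   equations this study assesses; see the vignette).
#' @param estimate When `FALSE`, skip fitting and build prediction
#'   intervals at the true parameters (a calibration check of the interval
#'   machinery itself); `beta` coverage is then omitted.
#' @param seed Integer seed for the whole study.
#' @return A tibble of class `coverage_result` with columns `nominal`,
#'   `target`, `actual`; per-replicate records are kept in attribute
#'   `"replicates"` and the number of excluded fits in `"n_failed"`.
#' @export
coverage_study <- function(scenario, B = 200L,
                           levels = seq(0.05, 0.95, by = 0.05),
                           fit_spacing = NULL, lattice_stride = 5L,
                           fit_options = list(), estimate = TRUE,
                           conditioning = c("leb_only", "all_data"),
                           seed = scenario$seed) {
  if (B < 50L) stop("`B` must be at least 50 replicates", call. = FALSE)
  conditioning <- match.arg(conditioning)
  opts <- utils::modifyList(list(n_starts = 5L, maxit = 120L, reltol = 1e-8),
                            fit_options)
  p_true <- scenario$true_params
  fit_grid <- if (is.null(fit_spacing)) scenario$sim_grid else
    build_quadrature_grid(scenario$units, fit_spacing, quiet = TRUE,
                          on_empty = "centroid")

  # continuous-prediction lattice: a regular thinning of the simulation
  # grid restricted to points assigned to some coarse unit, so the true
  # surface is known exactly at every lattice point
  g <- scenario$sim_grid
  xs <- sort(unique(g$points[, 1L])); ys <- sort(unique(g$points[, 2L]))
  keep_x <- g$points[, 1L] %in% xs[seq(1L, length(xs), by = lattice_stride)]
  keep_y <- g$points[, 2L] %in% ys[seq(1L, length(ys), by = lattice_stride)]
  lat_idx <- which(keep_x & keep_y & !is.na(g$part_index$coarse))
  lattice <- tibble::tibble(x = g$points[lat_idx, 1L], y = g$points[lat_idx, 2L])

  scenario_chol(scenario)  # factor the simulation covariance once
  z_half <- stats::qnorm(0.5 + levels / 2)
  reps <- list(); n_failed <- 0L; fail_msgs <- character(0)

  run_all <- function() {
    for (bb in seq_len(B)) {
      data <- simulate_dataset(scenario, seed = NULL)
      truth <- attr(data, "truth")
      fit <- if (estimate) {
        tryCatch(
          fit_mle(data, fit_grid, variant = "full", n_starts = opts$n_starts,
                  control = list(maxit = opts$maxit, reltol = opts$reltol)),
          error = function(e) e, warning = function(w) w
        )
      } else {
        plugin_fit(p_true, data, fit_grid)
      }
      if (inherits(fit, "condition")) {
        n_failed <<- n_failed + 1L
        fail_msgs <<- c(fail_msgs, conditionMessage(fit))
        next
      }

      rec <- list(replicate = bb)
      if (estimate) {
        se <- sqrt(diag(fit$vcov)[c("beta1", "beta2")])
        est <- fit$th_hat[c("beta1", "beta2")]
        if (anyNA(se)) {
          n_failed <<- n_failed + 1L
          fail_msgs <<- c(fail_msgs, "missing standard errors")
          next
        }
        rec$z_beta1 <- (est[[1L]] - p_true$beta[1L]) / se[[1L]]
        rec$z_beta2 <- (est[[2L]] - p_true$beta[2L]) / se[[2L]]
      }

      ap <- areal_prediction(fit, conditioning = conditioning)
      true_areal <- c(p_true$alpha[1L] + p_true$beta[1L] * truth$ubar_coarse,
                      p_true$alpha[2L] + p_true$beta[2L] * truth$ubar_coarse)
      z_areal <- (ap$mean - true_areal) / pmax(ap$sd, 1e-12)

      pf <- predictive_distribution(fit, lattice, conditioning = conditioning,
                                    keep_cov = FALSE)
      true_cont <- c(p_true$alpha[1L] + p_true$beta[1L] * truth$U[lat_idx],
                     p_true$alpha[2L] + p_true$beta[2L] * truth$U[lat_idx])
      z_cont <- (c(pf$mean) - true_cont) / pmax(c(pf$sd), 1e-12)

      rec$cov_areal <- vapply(z_half, function(z) mean(abs(z_areal) <= z), 0)
      rec$cov_cont <- vapply(z_half, function(z) mean(abs(z_cont) <= z), 0)
      reps[[length(reps) + 1L]] <<- rec
    }
  }
  withr::with_seed(seed, run_all())

  if (!length(reps)) stop("all replicates failed to fit", call. = FALSE)
  out <- list()
  if (estimate) {
    zb1 <- vapply(reps, `[[`, 0, "z_beta1")
    zb2 <- vapply(reps, `[[`, 0, "z_beta2")
    out$beta1 <- vapply(z_half, function(z) mean(abs(zb1) <= z), 0)
    out$beta2 <- vapply(z_half, function(z) mean(abs(zb2) <= z), 0)
  }
  out$areal <- rowMeans(vapply(reps, `[[`, numeric(length(levels)), "cov_areal"))
  out$continuous <- rowMeans(vapply(reps, `[[`, numeric(length(levels)), "cov_cont"))

  res <- dplyr::bind_rows(lapply(names(out), function(t) {
    tibble::tibble(nominal = levels, target = t, actual = out[[t]])
  }))
  class(res) <- c("coverage_result", class(res))
  attr(res, "B") <- as.integer(B)
  attr(res, "n_used") <- length(reps)
  attr(res, "n_failed") <- n_failed
  attr(res, "fail_messages") <- fail_msgs
  attr(res, "seed") <- as.integer(seed)
  attr(res, "replicates") <- reps
  res
}

#' Plot actual against nominal coverage
#'
#' One panel per target, with the identity line as the reference for
#' perfect calibration.
#'
#' @param object A [coverage_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_result
#' @export
autoplot.coverage_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$nominal, y = .data$actual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~target) +
    ggplot2::coord_equal(xlim = 0:1, ylim = 0:1) +
    ggplot2::labs(x = "nominal coverage", y = "actual coverage")
}

#' Write a coverage study as CSV
#'
#' @param result A [coverage_study()] result.
#' @param path Output CSV path.
#' @return The tibble, invisibly.
#' @export
write_coverage <- function(result, path) {
  utils::write.csv(tibble::as_tibble(result), path, row.names = FALSE)
  invisible(tibble::as_tibble(result))
}
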