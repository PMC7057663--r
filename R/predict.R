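#' Build a prediction lattice over the study region
#'
#' Regular lattice of cell centres at the requested resolution, keeping the
#' points that fall inside the union of the polygons of one partition
#' (the study region is the union of the coarse units by default).
#'
#' @param units Units tibble from [area_units()].
#' @param spacing Lattice resolution in metres (default 250).
#' @param partition Partition whose union defines the region.
#' @return Tibble with columns `x`, `y`; the spacing is kept as an
#'   attribute.
#' @export
prediction_lattice <- function(units, spacing = 250, partition = "coarse") {
  stopifnot(spacing > 0)
  sub <- units[units$partition == partition, , drop = FALSE]
  if (!nrow(sub)) stop("no units in partition ", partition, call. = FALSE)
  bb <- units_bbox(sub)
  xs <- seq(bb["xmin"] + spacing / 2, bb["xmax"], by = spacing)
  ys <- seq(bb["ymin"] + spacing / 2, bb["ymax"], by = spacing)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- logical(nrow(pts))
  for (g in sub$geometry) inside <- inside | points_in_polygon(pts, g)
  if (!any(inside)) stop("no lattice points fall inside the region", call. = FALSE)
  out <- tibble::tibble(x = pts[inside, 1L], y = pts[inside, 2L])
  attr(out, "spacing") <- spacing
  out
}

#' Predictive distribution of the outcome surfaces
#'
#' Gaussian conditional distribution of the spatially continuous outcome
#' `LEB_i(x) = alpha_i + beta_i U(x)` for both groups over a lattice, given
#' the observed data, with all parameters plugged in at their estimates.
#' All cross-covariances are derived from the single joint Gaussian model,
#' so prediction, areal aggregation and the likelihood are mutually
#' consistent. By default the conditioning set is the full data vector
#' (both outcome groups and the covariate); `conditioning = "leb_only"`
#' conditions on the outcome vectors alone.
#'
#' @param fit An `arealgp_fit`.
#' @param lattice Tibble from [prediction_lattice()], or any two-column
#'   matrix/data frame of planar coordinates.
#' @param conditioning `"all_data"` (default) or `"leb_only"`.
#' @param keep_cov Keep the full joint predictive covariance (needed for
#'   [sample_predictive()]). Default: only when the lattice has at most
#'   1500 points.
#' @return An object of class `predictive_field` with per-point predictive
#'   means and standard deviations for both groups.
#' @export
predictive_distribution <- function(fit, lattice,
                                    conditioning = c("all_data", "leb_only"),
                                    keep_cov = NULL) {
  conditioning <- match.arg(conditioning)
  pts <- as.matrix(as.data.frame(lattice)[, 1:2])
  q <- nrow(pts)
  if (q < 1L) stop("empty prediction lattice", call. = FALSE)
  if (is.null(keep_cov)) keep_cov <- q <= 1500L
  p <- fit$params_hat; grid <- fit$grid; data <- fit$data
  b <- p$beta; n <- n_coarse(data); m <- n_fine(data)

  kx_c <- point_unit_kernel(pts, grid, p$delta, "coarse")  # q x n
  if (conditioning == "all_data") {
    Sigma <- build_joint_covariance(p, data, grid)
    kx_f <- point_unit_kernel(pts, grid, p$delta, "fine")  # q x m
    cross_one <- function(i) {
      cbind(b[i] * b[1L] * p$tau2 * kx_c, b[i] * b[2L] * p$tau2 * kx_c,
            b[i] * p$tau2 * kx_f)
    }
    resid <- stacked_vector(data) - joint_mean(p, n, m)
  } else {
    F <- kernel_factors(grid, p$delta)
    S_cc <- p$tau2 * F$cc
    In <- diag(n)
    Sigma <- rbind(
      cbind(b[1L]^2 * S_cc + p$omega[1L, 1L] * In,
            b[1L] * b[2L] * S_cc + p$omega[1L, 2L] * In),
      cbind(b[1L] * b[2L] * S_cc + p$omega[1L, 2L] * In,
            b[2L]^2 * S_cc + p$omega[2L, 2L] * In)
    )
    cross_one <- function(i) {
      cbind(b[i] * b[1L] * p$tau2 * kx_c, b[i] * b[2L] * p$tau2 * kx_c)
    }
    resid <- c(data$outcome[, 1L] - p$alpha[1L], data$outcome[, 2L] - p$alpha[2L])
  }

  Cross <- rbind(cross_one(1L), cross_one(2L))        # 2q x N
  R <- chol_jitter(Sigma)
  u <- backsolve(R, resid, transpose = TRUE)
  W <- backsolve(R, t(Cross), transpose = TRUE)       # N x 2q
  mean_vec <- rep(p$alpha, each = q) + drop(crossprod(W, u))
  prior_var <- rep(b^2 * p$tau2, each = q)
  var_vec <- pmax(prior_var - colSums(W^2), 0)

  cov <- NULL
  if (keep_cov) {
    Kxx <- exp(-pair_dist(pts, pts) / p$delta)
    prior <- rbind(cbind(b[1L]^2 * Kxx, b[1L] * b[2L] * Kxx),
                   cbind(b[1L] * b[2L] * Kxx, b[2L]^2 * Kxx)) * p$tau2
    cov <- prior - crossprod(W)
  }

  structure(
    list(points = tibble::tibble(x = pts[, 1L], y = pts[, 2L]),
         mean = cbind(mean_vec[seq_len(q)], mean_vec[q + seq_len(q)]),
         sd = cbind(sqrt(var_vec[seq_len(q)]), sqrt(var_vec[q + seq_len(q)])),
         cov = cov, params = p, conditioning = conditioning,
         samples = NULL, seed = NULL),
    class = "predictive_field"
  )
}

#' @export
print.predictive_field <- function(x, ...) {
  cat("<predictive_field> ", nrow(x$points), " points, conditioning = ",
      x$conditioning, if (!is.null(x$cov)) ", joint covariance kept", "\n", sep = "")
  cat(sprintf("  group 1 mean range: %.2f-%.2f, group 2: %.2f-%.2f\n",
              min(x$mean[, 1L]), max(x$mean[, 1L]),
              min(x$mean[, 2L]), max(x$mean[, 2L])))
  invisible(x)
}

#' Draw joint samples from a predictive field
#'
#' Samples the full `2q`-dimensional Gaussian predictive distribution
#' (group-1 surface stacked over group-2); reproducible given `seed`.
#'
#' @param field A [predictive_distribution()] result with the covariance
#'   kept (`keep_cov = TRUE`).
#' @param n_draws Number of joint draws.
#' @param seed Integer seed.
#' @return The field with `samples` (`n_draws` x `2q` matrix) and `seed`
#'   filled in.
#' @export
sample_predictive <- function(field, n_draws, seed = 1L) {
  if (is.null(field$cov)) {
    stop("field has no joint covariance; rerun predictive_distribution() ",
         "with keep_cov = TRUE", call. = FALSE)
  }
  q2 <- nrow(field$cov)
  if (max(diag(field$cov)) <= .Machine$double.eps) {
    R <- matrix(0, q2, q2)
  } else {
    R <- chol_jitter(field$cov)
  }
  Z <- withr::with_seed(seed, matrix(stats::rnorm(n_draws * q2), n_draws, q2))
  field$samples <- sweep(Z %*% R, 2L, c(field$mean), "+")
  field$seed <- as.integer(seed)
  field
}

#' Non-exceedance probabilities
#'
#' `Pr(LEB_i(x) < l | data)` at every lattice point, in closed form from
#' the Gaussian predictive marginals.
#'
#' @param field A [predictive_distribution()] result.
#' @param group Outcome group, 1 or 2.
#' @param threshold Threshold `l` in outcome units (years).
#' @return Numeric vector of probabilities in \[0, 1\], one per point.
#' @export
nep <- function(field, group, threshold) {
  stopifnot(group %in% c(1L, 2L), is.finite(threshold))
  mu <- field$mean[, group]; sd <- field$sd[, group]
  out <- ifelse(sd > 0, stats::pnorm((threshold - mu) / sd),
                (mu < threshold) + 0.5 * (mu == threshold))
  as.numeric(out)
}

#' Classify non-exceedance probabilities
#'
#' Three-way classification against a threshold: values at or above `high`
#' mean the outcome is likely below the threshold, values at or below `low`
#' likely above it, anything else uncertain.
#'
#' @param nep_values Probabilities in \[0, 1\].
#' @param low,high Classification cut-offs, `0 < low < high < 1`.
#' @return Factor with levels `likely_above`, `uncertain`, `likely_below`.
#' @export
classify_nep <- function(nep_values, low = 0.2, high = 0.8) {
  if (!(low > 0 && high < 1 && low < high)) {
    stop("need 0 < low < high < 1", call. = FALSE)
  }
  lab <- ifelse(nep_values >= high, "likely_below",
                ifelse(nep_values <= low, "likely_above", "uncertain"))
  factor(lab, levels = c("likely_above", "uncertain", "likely_below"))
}

#' Areal predictions for the aggregated outcome
#'
#' Gaussian conditional of the noise-free unit-level outcome
#' `alpha_i + beta_i * Ubar_j` for every coarse unit, given the data, at
#' the plug-in parameter estimates, with central prediction intervals.
#'
#' @param fit An `arealgp_fit`.
#' @param level Interval coverage level.
#' @param conditioning `"all_data"` (default) or `"leb_only"`; see
#'   [predictive_distribution()].
#' @return Tibble with columns `id`, `group`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
areal_prediction <- function(fit, level = 0.95,
                             conditioning = c("all_data", "leb_only")) {
  conditioning <- match.arg(conditioning)
  p <- fit$params_hat; data <- fit$data; grid <- fit$grid
  b <- p$beta; n <- n_coarse(data); m <- n_fine(data)
  F <- kernel_factors(grid, p$delta)
  S_cc <- p$tau2 * F$cc; S_cf <- p$tau2 * F$cf

  if (conditioning == "all_data") {
    Sigma <- build_joint_covariance(p, data, grid)
    resid <- stacked_vector(data) - joint_mean(p, n, m)
    cross_one <- function(i) cbind(b[i] * b[1L] * S_cc, b[i] * b[2L] * S_cc, b[i] * S_cf)
  } else {
    In <- diag(n)
    Sigma <- rbind(
      cbind(b[1L]^2 * S_cc + p$omega[1L, 1L] * In,
            b[1L] * b[2L] * S_cc + p$omega[1L, 2L] * In),
      cbind(b[1L] * b[2L] * S_cc + p$omega[1L, 2L] * In,
            b[2L]^2 * S_cc + p$omega[2L, 2L] * In)
    )
    resid <- c(data$outcome[, 1L] - p$alpha[1L], data$outcome[, 2L] - p$alpha[2L])
    cross_one <- function(i) cbind(b[i] * b[1L] * S_cc, b[i] * b[2L] * S_cc)
  }
  Cross <- rbind(cross_one(1L), cross_one(2L))   # 2n x N
  R <- chol_jitter(Sigma)
  u <- backsolve(R, resid, transpose = TRUE)
  W <- backsolve(R, t(Cross), transpose = TRUE)
  mean_vec <- rep(p$alpha, each = n) + drop(crossprod(W, u))
  prior_var <- rep(b^2, each = n) * rep(diag(S_cc), 2L)
  sd_vec <- sqrt(pmax(prior_var - colSums(W^2), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    id = rep(data$coarse_ids, 2L), group = rep(1:2, each = n),
    mean = mean_vec, sd = sd_vec,
    lower = mean_vec - z * sd_vec, upper = mean_vec + z * sd_vec
  )
}

#' Plot a predictive field
#'
#' Tile maps of the predictive mean (and, when a threshold is supplied,
#' the non-exceedance probability) for one group.
#'
#' @param object A `predictive_field`.
#' @param group Outcome group to map.
#' @param threshold Optional threshold for a non-exceedance layer.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot predictive_field
#' @export
autoplot.predictive_field <- function(object, group = 1L, threshold = NULL, ...) {
  df <- object$points
  df$value <- object$mean[, group]
  df$layer <- "predictive mean (years)"
  if (!is.null(threshold)) {
    df2 <- object$points
    df2$value <- nep(object, group, threshold)
    df2$layer <- sprintf("NEP(l = %.1f)", threshold)
    df <- dplyr::bind_rows(df, df2)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = sprintf("Group %d outcome surface", group))
}
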