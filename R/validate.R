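#' Extract unit-level residuals
#'
#' Estimates the unstructured noise components `T_ij` as
#' `LEB_ij - alpha_i - beta_i * Uhat_j`, where `Uhat_j` is the Gaussian
#' conditional mean of the unit-averaged latent process given the full data
#' vector at the plug-in parameter estimates. Each residual pair is tagged
#' with the area-weighted centroid of its coarse unit, ready for the
#' variogram-based check of residual spatial correlation.
#'
#' @param fit An `arealgp_fit`.
#' @return Tibble with columns `id`, `x`, `y`, `t1`, `t2`.
#' @export
extract_residuals <- function(fit) {
  p <- fit$params_hat; data <- fit$data; grid <- fit$grid
  b <- p$beta; n <- n_coarse(data); m <- n_fine(data)
  F <- kernel_factors(grid, p$delta)
  S_cc <- p$tau2 * F$cc; S_cf <- p$tau2 * F$cf

  Sigma <- build_joint_covariance(p, data, grid)
  resid <- stacked_vector(data) - joint_mean(p, n, m)
  CrossU <- cbind(b[1L] * S_cc, b[2L] * S_cc, S_cf)   # n x (2n + m)
  R <- chol_jitter(Sigma)
  u <- backsolve(R, resid, transpose = TRUE)
  W <- backsolve(R, t(CrossU), transpose = TRUE)
  u_hat <- drop(crossprod(W, u))

  cents <- unit_centroids(grid_partition_units(grid, "coarse"))
  tibble::tibble(
    id = data$coarse_ids, x = cents$x, y = cents$y,
    t1 = data$outcome[, 1L] - p$alpha[1L] - b[1L] * u_hat,
    t2 = data$outcome[, 2L] - p$alpha[2L] - b[2L] * u_hat
  )
}

#' Distance bins for the residual variogram
#'
#' Equal-width bins; 12 bins on \[0, 10\] km by default, matching the
#' validation procedure for a city-sized domain. Supply `max_dist` (e.g.
#' half the domain diameter) for differently sized regions.
#'
#' @param n_bins Number of bins.
#' @param max_dist Upper edge of the last bin, metres.
#' @return Numeric vector of `n_bins + 1` bin edges.
#' @export
variogram_bins <- function(n_bins = 12L, max_dist = 10000) {
  stopifnot(n_bins >= 1L, max_dist > 0)
  seq(0, max_dist, length.out = n_bins + 1L)
}

# Pair structure shared by the empirical variogram and the permutations.
variogram_pairs <- function(xy, edges) {
  n <- nrow(xy)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((xy[ij[, 1L], 1L] - xy[ij[, 2L], 1L])^2 +
              (xy[ij[, 1L], 2L] - xy[ij[, 2L], 2L])^2)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= (length(edges) - 1L)
  list(i = ij[keep, 1L], j = ij[keep, 2L], bin = bin[keep],
       n_bins = length(edges) - 1L)
}

bin_semivariance <- function(values, pairs) {
  d2 <- (values[pairs$i] - values[pairs$j])^2
  sums <- rep(NA_real_, pairs$n_bins)
  cnt <- tabulate(pairs$bin, nbins = pairs$n_bins)
  agg <- rowsum(d2, pairs$bin)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  ifelse(cnt > 0L, sums / (2 * cnt), NA_real_)
}

#' Empirical semivariogram of unit residuals
#'
#' Per-bin semivariance `sum (t_j - t_k)^2 / (2 |U|)` over the centroid
#' pairs whose separation falls in each distance bin; each unordered pair
#' is counted once. Bins without pairs are reported as `NA`.
#'
#' @param residuals Tibble from [extract_residuals()] (columns `x`, `y`
#'   and `t1`/`t2`).
#' @param group Outcome group, 1 or 2.
#' @param bins Bin edges from [variogram_bins()].
#' @return Tibble with columns `bin`, `midpoint`, `n_pairs`, `gamma`.
#' @export
empirical_variogram <- function(residuals, group = 1L,
                                bins = variogram_bins()) {
  stopifnot(group %in% c(1L, 2L))
  xy <- cbind(residuals$x, residuals$y)
  pairs <- variogram_pairs(xy, bins)
  if (!length(pairs$i)) stop("no centroid pairs fall inside the bins", call. = FALSE)
  v <- residuals[[paste0("t", group)]]
  tibble::tibble(
    bin = seq_len(pairs$n_bins),
    midpoint = (bins[-length(bins)] + bins[-1L]) / 2,
    n_pairs = tabulate(pairs$bin, nbins = pairs$n_bins),
    gamma = bin_semivariance(v, pairs)
  )
}

#' Monte-Carlo tolerance envelope for the residual variogram
#'
#' Tests the assumption of no residual spatial correlation: residual values
#' are repeatedly permuted across the fixed unit centroids, the empirical
#' variogram is recomputed for each permutation, and pointwise tolerance
#' intervals are taken as per-bin quantiles of the permutation
#' distribution. The verdict for a group is `"inside"` when the observed
#' variogram lies within the envelope at every non-empty bin. No
#' multiplicity correction is applied across bins, matching the usual
#' presentation of this diagnostic; family-wise behaviour is assessed by
#' the calibration tests.
#'
#' @param residuals Tibble from [extract_residuals()].
#' @param group Groups to test (default both).
#' @param bins Bin edges from [variogram_bins()].
#' @param B Number of permutations (at least 100).
#' @param seed Integer seed.
#' @param level Tolerance level (default 0.95).
#' @return A tibble of class `variogram_envelope` with columns `group`,
#'   `bin`, `midpoint`, `n_pairs`, `empirical`, `lower`, `upper`, and a
#'   `verdicts` attribute (named character vector, `"inside"` /
#'   `"outside"`).
#' @export
permutation_envelope <- function(residuals, group = c(1L, 2L),
                                 bins = variogram_bins(), B = 1000L,
                                 seed = 1L, level = 0.95) {
  if (B < 100L) stop("`B` must be at least 100 permutations", call. = FALSE)
  xy <- cbind(residuals$x, residuals$y)
  pairs <- variogram_pairs(xy, bins)
  n <- nrow(xy)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  perms <- withr::with_seed(seed, replicate(B, sample.int(n), simplify = FALSE))
  out <- list(); verdicts <- character(0)
  for (g in group) {
    v <- residuals[[paste0("t", g)]]
    emp <- bin_semivariance(v, pairs)
    sims <- vapply(perms, function(p) bin_semivariance(v[p], pairs),
                   numeric(pairs$n_bins))
    qs <- apply(sims, 1L, stats::quantile, probs = probs, na.rm = TRUE,
                names = FALSE)
    ok <- is.finite(emp)
    inside <- all(emp[ok] >= qs[1L, ok] & emp[ok] <= qs[2L, ok])
    verdicts[as.character(g)] <- if (inside) "inside" else "outside"
    out[[as.character(g)]] <- tibble::tibble(
      group = g, bin = seq_len(pairs$n_bins),
      midpoint = (bins[-length(bins)] + bins[-1L]) / 2,
      n_pairs = tabulate(pairs$bin, nbins = pairs$n_bins),
      empirical = emp, lower = qs[1L, ], upper = qs[2L, ]
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("variogram_envelope", class(res))
  attr(res, "verdicts") <- verdicts
  attr(res, "B") <- as.integer(B)
  attr(res, "seed") <- as.integer(seed)
  attr(res, "level") <- level
  res
}

#' Plot a variogram tolerance envelope
#'
#' Observed per-bin semivariances as points over the permutation envelope
#' (dashed lines), one panel per group.
#'
#' @param object A [permutation_envelope()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variogram_envelope
#' @export
autoplot.variogram_envelope <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$group <- paste("group", df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint / 1000)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = 2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = 2, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$empirical), na.rm = TRUE) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "distance (km)", y = "semivariance",
                  title = "Residual variogram with permutation envelope")
}

#' Write variogram envelope plot data
#'
#' CSV with one row per (group, bin): midpoint, observed semivariance and
#' the envelope bounds.
#'
#' @param envelope A [permutation_envelope()] result.
#' @param path Output CSV path.
#' @return The exported tibble, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  utils::write.csv(tibble::as_tibble(envelope), path, row.names = FALSE)
  invisible(tibble::as_tibble(envelope))
}
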