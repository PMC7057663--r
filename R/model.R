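#' Exponential covariance kernel
#'
#' Stationary isotropic exponential covariance of the latent process:
#' `tau2 * exp(-distance / delta)`.
#'
#' @param distance Non-negative distance(s) in metres.
#' @param tau2 Variance (> 0).
#' @param delta Scale in metres (> 0).
#' @return Covariance value(s) in (0, `tau2`].
#' @examples
#' exp_cov(2000, 1, 2000)  # exp(-1)
#' @export
exp_cov <- function(distance, tau2, delta) {
  if (any(distance < 0)) stop("`distance` must be non-negative", call. = FALSE)
  if (tau2 <= 0 || delta <= 0) stop("`tau2` and `delta` must be positive", call. = FALSE)
  tau2 * exp(-distance / delta)
}

# Cholesky with escalating diagonal jitter. The pairwise-mean quadrature
# approximation of a valid kernel can be numerically indefinite, so a small
# ridge relative to the diagonal scale is added before factorization.
chol_jitter <- function(S, start = 1e-8, max_jitter = 1e-4) {
  scale <- mean(diag(S))
  j <- start
  repeat {
    R <- tryCatch(chol(S + diag(j * scale, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    j <- j * 100
    if (j > max_jitter) {
      ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
      stop("covariance matrix is not positive definite even after jitter ",
           "(smallest eigenvalue ", signif(ev, 3), ")", call. = FALSE)
    }
  }
}

# Gaussian log-density via Cholesky; resid is y - mean.
dmvn_chol <- function(resid, S) {
  R <- chol_jitter(S)
  z <- backsolve(R, resid, transpose = TRUE)
  -0.5 * length(resid) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Model-implied covariance blocks given the kernel factors F (from
# kernel_factors()). S_cc/S_ff/S_cf are covariances of the unit-averaged
# latent process within/between partitions.
latent_blocks <- function(params, F) {
  list(S_cc = params$tau2 * F$cc, S_ff = params$tau2 * F$ff,
       S_cf = params$tau2 * F$cf)
}

#' Joint covariance matrix of the stacked data vector
#'
#' Covariance of `(LEB_1, LEB_2, IMD)` implied by the model: the outcome
#' blocks are `beta_i * beta_i' * Sigma_coarse` plus the `omega` noise terms
#' on the respective (co-)diagonals, the covariate block is
#' `Sigma_fine + nu2 * I`, and the cross blocks have entries
#' `beta_i * tau2 * f(coarse_j, fine_k) / (|coarse_j| |fine_k|)`.
#'
#' @param params A [model_params()] object.
#' @param data A [misaligned_data()] object.
#' @param grid Quadrature grid over the same units.
#' @return A `(2n + m) x (2n + m)` symmetric matrix, rows ordered as group-1
#'   outcome, group-2 outcome, covariate.
#' @export
build_joint_covariance <- function(params, data, grid) {
  check_data_grid(data, grid)
  F <- kernel_factors(grid, params$delta)
  B <- latent_blocks(params, F)
  n <- n_coarse(data); m <- n_fine(data)
  b <- params$beta; Om <- params$omega
  In <- diag(n)
  S11 <- b[1L]^2 * B$S_cc + Om[1L, 1L] * In
  S22 <- b[2L]^2 * B$S_cc + Om[2L, 2L] * In
  S12 <- b[1L] * b[2L] * B$S_cc + Om[1L, 2L] * In
  C1 <- b[1L] * B$S_cf
  C2 <- b[2L] * B$S_cf
  SII <- B$S_ff + params$nu2 * diag(m)
  rbind(cbind(S11, S12, C1),
        cbind(S12, S22, C2),
        cbind(t(C1), t(C2), SII))
}

joint_mean <- function(params, n, m) {
  c(rep(params$alpha[1L], n), rep(params$alpha[2L], n), rep(params$gamma, m))
}

stacked_vector <- function(data) {
  c(data$outcome[, 1L], data$outcome[, 2L], data$covariate)
}

#' Gaussian log-likelihood of the joint model
#'
#' The default path evaluates the likelihood through its factorization into
#' the marginal density of the covariate vector and the conditional density
#' of the stacked outcome given the covariate; `method = "joint"` evaluates
#' the equivalent log-density of the full stacked Gaussian vector directly.
#' The two agree to numerical tolerance and the identity is enforced by the
#' test-suite.
#'
#' @param params A [model_params()] object.
#' @param data A [misaligned_data()] object.
#' @param grid Quadrature grid over the same units.
#' @param method `"factorized"` (default) or `"joint"`.
#' @return A single finite number.
#' @export
log_likelihood <- function(params, data, grid,
                           method = c("factorized", "joint")) {
  method <- match.arg(method)
  check_data_grid(data, grid)
  if (method == "joint") {
    S <- build_joint_covariance(params, data, grid)
    resid <- stacked_vector(data) - joint_mean(params, n_coarse(data), n_fine(data))
    return(dmvn_chol(resid, S))
  }
  F <- kernel_factors(grid, params$delta)
  loglik_factorized(params, data, F)
}

# Factorized evaluation sharing precomputed kernel factors; the workhorse
# behind both log_likelihood() and the optimizer.
loglik_factorized <- function(params, data, F) {
  B <- latent_blocks(params, F)
  n <- nrow(data$outcome); m <- length(data$covariate)
  b <- params$beta; Om <- params$omega

  # Marginal of the covariate: mean gamma, covariance S_ff + nu2 I.
  S_I <- B$S_ff + diag(params$nu2, m)
  r_I <- data$covariate - params$gamma
  R_I <- chol_jitter(S_I)
  u <- backsolve(R_I, r_I, transpose = TRUE)
  ll_I <- -0.5 * m * log(2 * pi) - sum(log(diag(R_I))) - 0.5 * sum(u^2)

  # Conditional of the stacked outcome given the covariate.
  Ct <- rbind(b[1L] * B$S_cf, b[2L] * B$S_cf)        # 2n x m
  W <- backsolve(R_I, t(Ct), transpose = TRUE)       # m x 2n
  mu <- c(rep(params$alpha[1L], n), rep(params$alpha[2L], n)) + drop(crossprod(W, u))
  In <- diag(n)
  S_L <- rbind(
    cbind(b[1L]^2 * B$S_cc + Om[1L, 1L] * In, b[1L] * b[2L] * B$S_cc + Om[1L, 2L] * In),
    cbind(b[1L] * b[2L] * B$S_cc + Om[1L, 2L] * In, b[2L]^2 * B$S_cc + Om[2L, 2L] * In)
  )
  S_cond <- S_L - crossprod(W)
  ll_L <- dmvn_chol(c(data$outcome[, 1L], data$outcome[, 2L]) - mu, S_cond)
  ll_I + ll_L
}

# ---- maximum likelihood -------------------------------------------------

# Method-of-moments starting values: intercepts from sample means, a 50/50
# variance split of the covariate between spatial and nugget components,
# delta at a quarter of the domain diameter, and beta from an OLS fit of
# each outcome on the coarse-averaged covariate (averaging weights given by
# shared quadrature points).
moment_init <- function(data, grid, variant) {
  y <- data$outcome; v <- data$covariate
  if (stats::var(v) == 0) {
    stop("covariate is constant; the association parameters are unidentifiable",
         call. = FALSE)
  }
  idx <- !is.na(grid$part_index$coarse) & !is.na(grid$part_index$fine)
  wtab <- table(grid$part_index$coarse[idx], grid$part_index$fine[idx])
  Wm <- matrix(as.numeric(wtab), nrow(wtab), ncol(wtab))
  v_bar <- drop(Wm %*% v[as.integer(colnames(wtab))]) / rowSums(Wm)
  v_bar_full <- rep(mean(v), nrow(y))
  v_bar_full[as.integer(rownames(wtab))] <- v_bar

  beta <- c(0, 0); resid <- sweep(y, 2L, colMeans(y))
  if (variant == "full") {
    fits <- lapply(1:2, function(i) stats::lm(y[, i] ~ v_bar_full))
    beta <- vapply(fits, function(f) stats::coef(f)[[2L]], 0)
    resid <- vapply(fits, stats::residuals, numeric(nrow(y)))
  }
  Om <- stats::cov(resid)
  # keep the starting correlation away from its boundary: near-singular
  # omega is a known degenerate mode of the likelihood
  rho <- min(max(Om[1L, 2L] / sqrt(Om[1L, 1L] * Om[2L, 2L]), -0.7), 0.7)
  vv <- stats::var(v)
  p <- model_params(
    alpha = colMeans(y) - beta * mean(v_bar_full), beta = beta, gamma = mean(v),
    tau2 = vv / 2, delta = domain_diameter(grid$units) / 4, nu2 = vv / 2,
    omega = c(max(Om[1L, 1L], 1e-4), max(Om[2L, 2L], 1e-4),
              rho * sqrt(max(Om[1L, 1L], 1e-4) * max(Om[2L, 2L], 1e-4)))
  )
  params_to_th(p, variant)
}

# Negative log-likelihood closure with a small LRU cache of kernel factors
# keyed on delta: numerical derivatives with respect to the non-spatial
# parameters reuse the quadrature aggregation, and fresh delta values go
# through the histogram-accelerated factor path.
make_nll <- function(data, grid, variant) {
  cache <- list()
  get_F <- function(delta) {
    key <- sprintf("%.17g", delta)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    F <- kernel_factors_fast(grid, delta)
    if (length(cache) >= 4L) cache[-1L] <<- NULL
    cache[[key]] <<- F
    F
  }
  function(th) {
    names(th) <- th_names(variant)
    p <- tryCatch(th_to_params(th, variant), error = function(e) NULL)
    if (is.null(p) || !all(is.finite(unlist(p[c("tau2", "delta", "nu2")])))) {
      return(1e10)
    }
    ll <- tryCatch(loglik_factorized(p, data, get_F(p$delta)),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

#' Fit the joint model by maximum likelihood
#'
#' Maximises the exact Gaussian likelihood over the unconstrained
#' parameterization (variances on the log scale, the cross-group covariance
#' through the inverse hyperbolic tangent of its correlation). A
#' method-of-moments initialization is refined by quasi-Newton (BFGS)
#' optimisation with numerical gradients; additional randomly perturbed
#' starts guard against the known likelihood ridge in `(tau2, delta)`.
#' Wald 95% confidence intervals come from the inverse observed information
#' on the transformed scale.
#'
#' @param data A [misaligned_data()] object.
#' @param grid Quadrature grid over the same units.
#' @param variant `"full"`, or `"no_covariate"` for the nested model with
#'   `beta1 = beta2 = 0`.
#' @param init Optional [model_params()] starting values (default:
#'   method of moments).
#' @param n_starts Number of optimisation starts (1 = moment start only).
#' @param seed Seed for the random multi-start perturbations.
#' @param adaptive When `TRUE` (default) the random extra starts are only
#'   run if the moment-initialised solution lands on the known likelihood
#'   ridge (degenerate `tau2` or a correlation range far beyond the
#'   domain); `FALSE` always runs all `n_starts` starts.
#' @param control List of optimizer options: `maxit` (default 300),
#'   `reltol` (default 1e-10), `hessian` (compute the observed information,
#'   default TRUE).
#' @return An object of class `arealgp_fit`.
#' @export
fit_mle <- function(data, grid, variant = c("full", "no_covariate"),
                    init = NULL, n_starts = 5L, seed = 1L, adaptive = TRUE,
                    control = list()) {
  variant <- match.arg(variant)
  check_data_grid(data, grid, min_units = 3L)
  ctrl <- utils::modifyList(list(maxit = 300L, reltol = 1e-10, hessian = TRUE),
                            control)
  nll <- make_nll(data, grid, variant)
  th0 <- if (is.null(init)) moment_init(data, grid, variant)
         else params_to_th(init, variant)

  starts <- list(th0)
  if (n_starts > 1L) {
    # deterministic "spatial-heavy" alternative: most of the covariate
    # variance spatial, short correlation range — the opposite corner of
    # the (tau2, delta) ridge from typical moment starts
    th_sp <- th0
    v_var <- stats::var(data$covariate)
    th_sp[["log_tau2"]] <- log(0.8 * v_var)
    th_sp[["log_nu2"]] <- log(0.2 * v_var)
    th_sp[["log_delta"]] <- log(domain_diameter(grid$units) / 10)
    th_sp[["atanh_rho"]] <- 0
    starts[[2L]] <- th_sp
  }
  if (n_starts > 2L) {
    sds <- c(alpha1 = 0.5, alpha2 = 0.5, beta1 = 0.05, beta2 = 0.05,
             gamma = 1, log_tau2 = 0.7, log_delta = 0.7, log_nu2 = 0.7,
             log_omega1_sq = 0.7, log_omega2_sq = 0.7, atanh_rho = 0.3)
    sds <- sds[th_names(variant)]
    starts <- c(starts, withr::with_seed(seed, lapply(seq_len(n_starts - 2L), function(s) {
      th0 + stats::rnorm(length(th0), sd = sds)
    })))
  }

  # pathology heuristic for adaptive multi-start: collapsed or exploded
  # spatial variance, correlation range dwarfing the region, a cross-group
  # correlation at its boundary, or an absurd effect size
  v_scale <- stats::var(data$covariate)
  y_scale <- stats::var(c(data$outcome))
  diam <- domain_diameter(grid$units)
  pathological <- function(th) {
    p <- th_to_params(th, variant)
    p$tau2 < 1e-4 * v_scale || p$tau2 > 1e4 * v_scale ||
      p$delta > 2 * diam || p$delta < grid$spacing / 2 ||
      abs(cross_group_correlation(p$omega)) > 0.99 ||
      min(diag(p$omega)) < 1e-5 * y_scale ||
      max(abs(p$beta)) * sqrt(v_scale) > 5 * sqrt(y_scale)
  }

  # Keep the best solution overall and the best non-degenerate one; a
  # boundary mode (singular omega, collapsed tau2) can interpolate the
  # data and spuriously dominate the likelihood, so a non-degenerate
  # optimum is preferred whenever one is found.
  best <- NULL; best_ok <- NULL
  diag_log <- list()
  for (s in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[s]], nll, method = "BFGS",
                   control = list(maxit = ctrl$maxit, reltol = ctrl$reltol)),
      error = function(e) NULL
    )
    diag_log[[s]] <- if (is.null(opt)) "error" else opt$convergence
    if (!is.null(opt) && opt$value < 1e10) {
      if (is.null(best) || opt$value < best$value) best <- opt
      if (!pathological(opt$par) &&
          (is.null(best_ok) || opt$value < best_ok$value)) {
        best_ok <- opt
      }
    }
    if (adaptive && !is.null(best_ok)) break
  }
  if (!is.null(best_ok)) {
    best <- best_ok
  } else if (!is.null(best)) {
    warning("all optimisation starts converged to a degenerate boundary ",
            "mode; reporting the best of them", call. = FALSE)
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    stop("maximum-likelihood optimisation failed from all ", length(starts),
         " starts (", paste(unlist(diag_log), collapse = ", "), ")", call. = FALSE)
  }

  th_hat <- stats::setNames(best$par, th_names(variant))
  vcov_th <- NULL
  if (isTRUE(ctrl$hessian)) {
    H <- tryCatch(stats::optimHess(th_hat, nll), error = function(e) NULL)
    if (!is.null(H)) {
      vcov_th <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov_th) && any(diag(vcov_th) <= 0)) {
        # fall back to a pseudo-inverse when the observed information is
        # numerically singular along a ridge
        e <- eigen(H, symmetric = TRUE)
        pos <- e$values > max(e$values) * 1e-10
        vcov_th <- e$vectors[, pos, drop = FALSE] %*%
          (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
        warning("observed information is near-singular; ",
                "confidence intervals use a pseudo-inverse", call. = FALSE)
      }
      if (!is.null(vcov_th)) dimnames(vcov_th) <- list(names(th_hat), names(th_hat))
    }
  }

  structure(
    list(params_hat = th_to_params(th_hat, variant), th_hat = th_hat,
         loglik = -best$value, vcov = vcov_th, variant = variant,
         convergence = list(code = best$convergence, counts = best$counts,
                            starts = unlist(diag_log)),
         n_starts = length(starts), seed = seed,
         data = data, grid = grid),
    class = "arealgp_fit"
  )
}

#' Recast known parameters as a fitted-model object
#'
#' Wraps a parameter set as an `arealgp_fit` without optimisation, so that
#' the prediction, residual and validation machinery can be run at known
#' (e.g. simulation-true) parameter values. No covariance of the estimates
#' is available.
#'
#' @param params A [model_params()] object.
#' @inheritParams fit_mle
#' @return An object of class `arealgp_fit`.
#' @export
plugin_fit <- function(params, data, grid,
                       variant = if (all(params$beta == 0)) "no_covariate" else "full") {
  check_data_grid(data, grid)
  structure(
    list(params_hat = params, th_hat = params_to_th(params, variant),
         loglik = log_likelihood(params, data, grid), vcov = NULL,
         variant = variant, convergence = list(code = NA_integer_),
         n_starts = 0L, seed = NA_integer_, data = data, grid = grid),
    class = "arealgp_fit"
  )
}

#' @export
print.arealgp_fit <- function(x, ...) {
  cat("<arealgp_fit> variant = ", x$variant, ", log-likelihood = ",
      sprintf("%.3f", x$loglik), "\n", sep = "")
  print(x$params_hat)
  invisible(x)
}

#' @export
logLik.arealgp_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$th_hat), class = "logLik")
}

#' @export
coef.arealgp_fit <- function(object, ...) object$th_hat

#' @export
vcov.arealgp_fit <- function(object, ...) object$vcov

#' @export
confint.arealgp_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$vcov)) stop("no estimate covariance available", call. = FALSE)
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$th_hat - z * se, object$th_hat + z * se)
  colnames(ci) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Tidy the fitted model
#'
#' One row per estimated parameter on the reporting scale (intercepts and
#' regression coefficients natural, variances as logs, the cross-group
#' covariance as `atanh` of its correlation), with Wald standard errors and
#' confidence limits.
#'
#' @param x An `arealgp_fit`.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy arealgp_fit
#' @export
tidy.arealgp_fit <- function(x, conf.level = 0.95, ...) {
  se <- if (is.null(x$vcov)) rep(NA_real_, length(x$th_hat)) else sqrt(diag(x$vcov))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$th_hat), estimate = unname(x$th_hat), std.error = unname(se),
    conf.low = unname(x$th_hat - z * se), conf.high = unname(x$th_hat + z * se)
  )
}

#' Glance at the fitted model
#'
#' @param x An `arealgp_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the log-likelihood, parameter count, data
#'   dimensions, model variant and convergence code.
#' @method glance arealgp_fit
#' @export
glance.arealgp_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, df = length(x$th_hat),
    n_coarse = n_coarse(x$data), n_fine = n_fine(x$data),
    variant = x$variant, convergence = x$convergence$code
  )
}

#' Fraction of outcome variance explained by the shared spatial process
#'
#' `beta^2 * tau2 / (beta^2 * tau2 + omega2)`: the share of the total
#' variance of one outcome group attributable to the latent deprivation
#' process rather than to unstructured noise.
#'
#' @param beta Regression coefficient of the group.
#' @param tau2 Latent process variance.
#' @param omega2 Noise variance of the group.
#' @return Fraction in \[0, 1); zero iff `beta = 0`.
#' @examples
#' variance_explained(-0.129, exp(6.226), exp(2.581))  # about 0.389
#' @export
variance_explained <- function(beta, tau2, omega2) {
  if (any(tau2 <= 0) || any(omega2 <= 0)) {
    stop("`tau2` and `omega2` must be positive", call. = FALSE)
  }
  beta^2 * tau2 / (beta^2 * tau2 + omega2)
}

#' Cross-group residual correlation
#'
#' `omega12 / (omega1 * omega2)` from the noise covariance of the two
#' outcome groups.
#'
#' @param omega 2 x 2 covariance matrix, or a [model_params()] /
#'   `arealgp_fit` object.
#' @return Correlation in (-1, 1).
#' @export
cross_group_correlation <- function(omega) {
  if (inherits(omega, "arealgp_fit")) omega <- omega$params_hat
  if (inherits(omega, "model_params")) omega <- omega$omega
  omega <- as.matrix(omega)
  omega[1L, 2L] / sqrt(omega[1L, 1L] * omega[2L, 2L])
}

#' Practical range of the spatial correlation
#'
#' The distance beyond which the exponential correlation falls below
#' `threshold`: `-delta * log(threshold)`.
#'
#' @param delta Spatial scale in metres.
#' @param threshold Correlation threshold in (0, 1\].
#' @return Distance in metres.
#' @examples
#' practical_range(exp(7.336)) / 1000  # about 4.6 km
#' @export
practical_range <- function(delta, threshold = 0.05) {
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]", call. = FALSE)
  -delta * log(threshold)
}

#' Likelihood-ratio test of the no-association model
#'
#' Tests `beta1 = beta2 = 0` by comparing the full fit with the nested
#' no-covariate fit on the same data; the statistic is referred to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param full Full-model `arealgp_fit`.
#' @param reduced No-covariate `arealgp_fit` on the same data.
#' @return A one-row tibble with `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(full, reduced) {
  if (full$variant != "full" || reduced$variant != "no_covariate") {
    stop("`full` must be the full fit and `reduced` the no-covariate fit",
         call. = FALSE)
  }
  if (!identical(full$data$outcome, reduced$data$outcome)) {
    stop("the two fits are not on the same data", call. = FALSE)
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  tibble::tibble(statistic = stat, df = 2L,
                 p.value = stats::pchisq(stat, df = 2L, lower.tail = FALSE))
}

#' Write a plain-text fit report
#'
#' Tabulates estimates and 95% confidence intervals for one or two fitted
#' models (typically the full and the no-covariate variants) in a
#' parameter-by-model layout, with the log-likelihoods in the final row,
#' and optionally writes it as CSV. For positive cross-group covariance a
#' derived `log_omega12` row with a delta-method interval is included.
#'
#' @param fit Full-model `arealgp_fit`.
#' @param reduced Optional second fit.
#' @param path Optional CSV output path.
#' @return The report tibble (invisibly when `path` is given).
#' @export
write_fit_report <- function(fit, reduced = NULL, path = NULL) {
  one <- function(f) {
    td <- tidy(f)
    lw12 <- derived_log_omega12(f)
    if (!is.null(lw12)) td <- dplyr::bind_rows(td, lw12)
    td <- dplyr::bind_rows(
      td, tibble::tibble(term = "log_likelihood", estimate = f$loglik,
                         std.error = NA_real_, conf.low = NA_real_,
                         conf.high = NA_real_))
    td[, c("term", "estimate", "conf.low", "conf.high")]
  }
  rep1 <- one(fit)
  names(rep1)[-1L] <- paste0(names(rep1)[-1L], "_", fit$variant)
  out <- rep1
  if (!is.null(reduced)) {
    rep2 <- one(reduced)
    names(rep2)[-1L] <- paste0(names(rep2)[-1L], "_", reduced$variant)
    out <- dplyr::full_join(rep1, rep2, by = "term")
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# log(omega12) = log(rho) + (log w1^2 + log w2^2)/2 for rho > 0, with a
# delta-method interval from the transformed-scale covariance.
derived_log_omega12 <- function(fit) {
  p <- fit$params_hat
  if (p$omega[1L, 2L] <= 0) return(NULL)
  rho <- cross_group_correlation(p$omega)
  est <- log(p$omega[1L, 2L])
  se <- NA_real_
  if (!is.null(fit$vcov)) {
    g <- stats::setNames(numeric(length(fit$th_hat)), names(fit$th_hat))
    g["log_omega1_sq"] <- 0.5
    g["log_omega2_sq"] <- 0.5
    g["atanh_rho"] <- (1 - rho^2) / rho
    se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  }
  tibble::tibble(term = "log_omega12", estimate = est, std.error = se,
                 conf.low = est - 1.96 * se, conf.high = est + 1.96 * se)
}
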