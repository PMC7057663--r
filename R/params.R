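#' Model parameter set
#'
#' Parameters of the joint model for a bivariate areal outcome and an areal
#' covariate sharing one latent Gaussian process `U(x)` with exponential
#' covariance `tau2 * exp(-distance / delta)`:
#' \deqn{LEB_{ij} = \alpha_i + \beta_i \bar U_j + T_{ij}, \qquad
#'       IMD_k = \gamma + \bar U^*_k + V_k,}
#' where `(T_{1j}, T_{2j})` are iid bivariate normal with covariance
#' `omega`, and `V_k` are iid normal with variance `nu2`.
#'
#' @param alpha Length-2 intercepts of the outcome (years).
#' @param beta Length-2 regression coefficients on the latent process
#'   (outcome units per covariate unit).
#' @param gamma Covariate intercept.
#' @param tau2 Variance of the latent process (> 0).
#' @param delta Spatial correlation scale in metres (> 0).
#' @param nu2 Covariate nugget variance (> 0).
#' @param omega 2 x 2 positive-definite covariance of the outcome noise
#'   pair, or length-3 vector `c(omega1_sq, omega2_sq, omega12)`.
#' @return An object of class `model_params`.
#' @examples
#' model_params(alpha = c(75, 81), beta = c(-0.15, -0.13), gamma = 39,
#'              tau2 = 500, delta = 1500, nu2 = 13, omega = c(6, 13, 5))
#' @export
model_params <- function(alpha, beta, gamma, tau2, delta, nu2, omega) {
  if (length(alpha) != 2L || length(beta) != 2L) {
    stop("`alpha` and `beta` must have length 2", call. = FALSE)
  }
  if (length(omega) == 3L) {
    omega <- matrix(c(omega[1L], omega[3L], omega[3L], omega[2L]), 2L, 2L)
  }
  omega <- unname(as.matrix(omega))
  if (!isTRUE(all.equal(omega, t(omega))) || any(dim(omega) != 2L)) {
    stop("`omega` must be a symmetric 2 x 2 matrix", call. = FALSE)
  }
  for (nm in c("gamma", "tau2", "delta", "nu2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (tau2 <= 0 || delta <= 0 || nu2 <= 0) {
    stop("`tau2`, `delta` and `nu2` must be positive", call. = FALSE)
  }
  if (omega[1L, 1L] <= 0 || omega[2L, 2L] <= 0 ||
      omega[1L, 2L]^2 >= omega[1L, 1L] * omega[2L, 2L]) {
    stop("`omega` must be positive definite", call. = FALSE)
  }
  structure(
    list(alpha = unname(as.numeric(alpha)), beta = unname(as.numeric(beta)),
         gamma = as.numeric(gamma), tau2 = as.numeric(tau2),
         delta = as.numeric(delta), nu2 = as.numeric(nu2), omega = omega),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  alpha = (%.3f, %.3f)   beta = (%.4f, %.4f)   gamma = %.3f\n",
              x$alpha[1L], x$alpha[2L], x$beta[1L], x$beta[2L], x$gamma))
  cat(sprintf("  tau2 = %.3f   delta = %.1f m   nu2 = %.3f\n",
              x$tau2, x$delta, x$nu2))
  cat(sprintf("  omega: var1 = %.3f, var2 = %.3f, cov = %.3f (rho = %.3f)\n",
              x$omega[1L, 1L], x$omega[2L, 2L], x$omega[1L, 2L],
              cross_group_correlation(x$omega)))
  invisible(x)
}

#' Published Liverpool point estimates
#'
#' Maximum-likelihood point estimates from the joint analysis of male and
#' female life expectancy at birth (MSOA level) and the 2015 index of
#' multiple deprivation (LSOA level) for Liverpool, UK. These are the
#' default "true" parameters of the synthetic simulation scenarios.
#'
#' @param model `"full"` for the model with the deprivation association, or
#'   `"no_covariate"` for the nested model with both `beta` fixed at zero.
#' @return A [model_params()] object.
#' @examples
#' liverpool_params()$delta  # about 1534 m
#' @export
liverpool_params <- function(model = c("full", "no_covariate")) {
  model <- match.arg(model)
  if (model == "full") {
    model_params(
      alpha = c(75.466, 81.120), beta = c(-0.154, -0.129), gamma = 39.221,
      tau2 = exp(6.226), delta = exp(7.336), nu2 = exp(2.586),
      omega = c(exp(1.810), exp(2.581), exp(1.671))
    )
  } else {
    model_params(
      alpha = c(75.131, 81.375), beta = c(0, 0), gamma = 39.190,
      tau2 = exp(6.232), delta = exp(7.349), nu2 = exp(2.589),
      omega = c(exp(3.036), exp(3.160), exp(2.871))
    )
  }
}

# ---- unconstrained parameterization ------------------------------------
# Variances are optimised on the log scale and the cross-group covariance
# through z = atanh(rho), so omega stays positive definite and negative
# cross-covariance remains representable.

th_names <- function(variant) {
  nm <- c("alpha1", "alpha2", "beta1", "beta2", "gamma", "log_tau2",
          "log_delta", "log_nu2", "log_omega1_sq", "log_omega2_sq", "atanh_rho")
  if (variant == "no_covariate") nm <- setdiff(nm, c("beta1", "beta2"))
  nm
}

params_to_th <- function(p, variant = "full") {
  rho <- p$omega[1L, 2L] / sqrt(p$omega[1L, 1L] * p$omega[2L, 2L])
  th <- c(p$alpha, p$beta, p$gamma, log(p$tau2), log(p$delta), log(p$nu2),
          log(p$omega[1L, 1L]), log(p$omega[2L, 2L]), atanh(rho))
  names(th) <- th_names("full")
  if (variant == "no_covariate") th <- th[th_names(variant)]
  th
}

th_to_params <- function(th, variant = "full") {
  th <- stats::setNames(as.numeric(th), names(th))
  beta <- if (variant == "no_covariate") c(0, 0) else th[c("beta1", "beta2")]
  w1 <- exp(th[["log_omega1_sq"]]); w2 <- exp(th[["log_omega2_sq"]])
  rho <- tanh(th[["atanh_rho"]])
  model_params(
    alpha = c(th[["alpha1"]], th[["alpha2"]]), beta = beta,
    gamma = th[["gamma"]], tau2 = exp(th[["log_tau2"]]),
    delta = exp(th[["log_delta"]]), nu2 = exp(th[["log_nu2"]]),
    omega = c(w1, w2, rho * sqrt(w1 * w2))
  )
}
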