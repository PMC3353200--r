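#' Scale factor between mediator-conditional and mediator-marginal coefficients
#'
#' A binary-link coefficient is defined relative to the residual variance it
#' conditions on. Excluding the mediator folds `lambda^2 theta` extra variance
#' into the residual, so coefficients shrink by `sqrt(1 + lambda^2 theta)`
#' under the probit link and by
#' `sqrt((pi^2/3 + lambda^2 theta) / (pi^2/3))` under the logit link. For the
#' logit link the relation is approximate, because a normal plus a logistic
#' residual is not logistic.
#'
#' @param link `"probit"` or `"logit"`.
#' @param lambda Mediator-to-outcome loading.
#' @param theta Mediator residual variance (non-negative).
#' @return A single number, always at least 1.
#' @examples
#' scale_factor("probit", 1, 1)          # sqrt(2)
#' scale_factor("logit", 1, pi^2 / 3)    # sqrt(2)
#' @export
scale_factor <- function(link = c("probit", "logit"), lambda, theta) {
  link <- match.arg(link)
  if (theta < 0) abort("`theta` must be non-negative.")
  if (link == "probit") sqrt(1 + lambda^2 * theta)
  else sqrt((pi^2 / 3 + lambda^2 * theta) / (pi^2 / 3))
}

# d scale_factor / d (lambda, theta), for the delta method
scale_factor_grad <- function(link, lambda, theta) {
  s <- scale_factor(link, lambda, theta)
  base <- if (link == "probit") 1 else pi^2 / 3
  c(lambda * theta / (base * s), lambda^2 / (2 * base * s))
}

effect_estimate <- function(estimate, se, scale, method, approximate = FALSE) {
  tibble(method = method, scale = scale, estimate = estimate, se = se,
         ci_low = estimate - qnorm(0.975) * se,
         ci_high = estimate + qnorm(0.975) * se,
         p_value = 2 * pnorm(-abs(estimate / se)),
         approximate = approximate)
}

#' Rescale a mediator-excluded total-effect estimate to the conditional scale
#'
#' Multiplies the predictor coefficient of a mediator-excluded mixed-model
#' fit (a total effect on the mediator-marginal scale) and its standard error
#' by [scale_factor()], yielding an estimate comparable with
#' mediator-conditional coefficients such as the structural `kappa +
#' lambda * gamma1`. With `lam_theta_vcov` supplied, `lambda` and `theta` are
#' treated as estimates and their sampling uncertainty is propagated into the
#' SE by the delta method, assuming independence from the outcome fit.
#'
#' @param fit A `"medtotal_nlmm"` fit with the mediator excluded.
#' @param lambda,theta Scale-factor inputs: true values, or estimates
#'   (`beta_M` from a mediator-included fit, `theta_hat` from
#'   [fit_mediator_lm()]).
#' @param lam_theta_vcov Optional 2x2 covariance of `(lambda, theta)`; `NULL`
#'   (the default) means known true values.
#' @return A one-row tibble: `method`, `scale`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `approximate` (`TRUE` for the logit link, whose
#'   scaling is approximate).
#' @export
rescale_total_effect <- function(fit, lambda, theta, lam_theta_vcov = NULL) {
  stopifnot(inherits(fit, "medtotal_nlmm"))
  if (fit$spec$include_mediator) {
    abort("`fit` must exclude the mediator: its `z` coefficient is a total effect only then.")
  }
  link <- fit$spec$link
  s <- scale_factor(link, lambda, theta)
  b3 <- unname(fit$beta["z"])
  v3 <- fit$vcov_beta["z", "z"]
  est <- b3 * s
  if (is.null(lam_theta_vcov)) {
    se <- sqrt(v3) * s
    method <- "nlmm_scaled_true"
  } else {
    g <- scale_factor_grad(link, lambda, theta)
    var_s <- as.numeric(t(g) %*% as.matrix(lam_theta_vcov) %*% g)
    se <- sqrt(s^2 * v3 + b3^2 * var_s)
    method <- "nlmm_scaled_estimated"
  }
  effect_estimate(est, se, "conditional_on_mediator", method,
                  approximate = link == "logit")
}

#' Total effect by the product-of-coefficients route
#'
#' From a mediator-included mixed model (direct effect `beta_z`, mediator
#' path `beta_M`) and the mediator linear model (`alpha1`), the total effect
#' is `beta_z + alpha1 * beta_M` - the maximum-likelihood structural total
#' effect, since the joint likelihood factorises into the mediator model
#' times the conditional outcome model. The SE combines the within-fit
#' covariance of `(beta_z, beta_M)` with the variance of `alpha1` by the
#' delta method, treating the two fits as independent.
#'
#' @param outcome_fit A `"medtotal_nlmm"` fit with the mediator included.
#' @param mediator_fit A [fit_mediator_lm()] fit.
#' @return A one-row tibble as in [rescale_total_effect()], with
#'   `method = "sem_ml"`.
#' @export
product_of_coefficients <- function(outcome_fit, mediator_fit) {
  stopifnot(inherits(outcome_fit, "medtotal_nlmm"),
            inherits(mediator_fit, "medtotal_medlm"))
  if (!outcome_fit$spec$include_mediator) {
    abort("`outcome_fit` must include the mediator (its `z` coefficient is the direct effect).")
  }
  b3 <- unname(outcome_fit$beta["z"])
  b4 <- unname(outcome_fit$beta["M"])
  a1 <- mediator_fit$alpha1
  V <- outcome_fit$vcov_beta
  va1 <- mediator_fit$vcov["alpha1", "alpha1"]
  est <- b3 + a1 * b4
  se <- sqrt(V["z", "z"] + a1^2 * V["M", "M"] + 2 * a1 * V["z", "M"] + b4^2 * va1)
  effect_estimate(est, se, "conditional_on_mediator", "sem_ml")
}

#' Unscaled total-effect estimate from a mediator-excluded fit
#'
#' The raw predictor coefficient of the mediator-excluded mixed model: a
#' total effect on the mediator-marginal scale, smaller than the conditional
#' total effect by the scale factor.
#'
#' @param fit A `"medtotal_nlmm"` fit with the mediator excluded.
#' @return A one-row tibble as in [rescale_total_effect()], with
#'   `scale = "marginal_of_mediator"` and `method = "nlmm_unscaled"`.
#' @export
unscaled_total_effect <- function(fit) {
  stopifnot(inherits(fit, "medtotal_nlmm"))
  if (fit$spec$include_mediator) abort("`fit` must exclude the mediator.")
  effect_estimate(unname(fit$beta["z"]), sqrt(fit$vcov_beta["z", "z"]),
                  "marginal_of_mediator", "nlmm_unscaled",
                  approximate = fit$spec$link == "logit")
}

#' Population target of the mediator-excluded mixed model
#'
#' The conditional total effect `kappa + lambda * gamma1` divided by the
#' scale factor: the value the mediator-excluded model estimates. Exact for
#' the probit link; an approximation for the logit link (flagged by the
#' `"approximate"` attribute).
#'
#' @param link `"probit"` or `"logit"`.
#' @param params A [true_params()] object.
#' @return A number with attribute `approximate` (`TRUE` for logit).
#' @examples
#' p <- make_scenario("probit", 0.3, "equal", nuisance_config(theta = 0.15))
#' unscaled_truth("probit", p)  # 0.3 / sqrt(1.15)
#' @export
unscaled_truth <- function(link = c("probit", "logit"), params) {
  link <- match.arg(link)
  stopifnot(inherits(params, "medtotal_params"))
  structure(total_effect(params) / scale_factor(link, params$lambda, params$theta),
            approximate = link == "logit")
}

#' All four total-effect estimates for one dataset
#'
#' Convenience wrapper fitting the mediator-excluded mixed model, the
#' mediator linear model and the mediator-included mixed model, and returning
#' the unscaled, true-scaled (if true parameters are supplied),
#' estimated-scale and product-of-coefficients total effects as one tibble.
#'
#' @param data Long-format data (see [fit_nlmm()]).
#' @param link `"probit"` or `"logit"`.
#' @param params Optional [true_params()]; when given, the true-parameter
#'   rescaling is included.
#' @param nodes Quadrature nodes per dimension.
#' @return A tibble of effect estimates, one row per method, plus a
#'   `converged` column.
#' @export
total_effect_estimates <- function(data, link = c("probit", "logit"),
                                   params = NULL, nodes = 15) {
  link <- match.arg(link)
  fit0 <- fit_nlmm(data, link, include_mediator = FALSE, nodes = nodes)
  fit1 <- fit_nlmm(data, link, include_mediator = TRUE, nodes = nodes)
  med <- fit_mediator_lm(data)
  lam_hat <- unname(fit1$beta["M"])
  vc <- diag(c(fit1$vcov_beta["M", "M"], med$theta_se^2))
  out <- dplyr::bind_rows(
    dplyr::mutate(unscaled_total_effect(fit0), converged = fit0$converged),
    if (!is.null(params)) {
      dplyr::mutate(rescale_total_effect(fit0, params$lambda, params$theta),
                    converged = fit0$converged)
    },
    dplyr::mutate(rescale_total_effect(fit0, lam_hat, med$theta_hat, vc),
                  converged = fit0$converged && fit1$converged),
    dplyr::mutate(product_of_coefficients(fit1, med),
                  converged = fit1$converged)
  )
  out
}
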