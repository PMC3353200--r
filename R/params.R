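#' Nuisance parameters of the generative model
#'
#' Collects the parts of the latent-growth structural equation model that do
#' not define the total effect of interest: the latent-intercept and
#' latent-slope means, the mediator intercept, the baseline-covariate path,
#' the mediator loading, the growth-factor covariance and the mediator
#' residual variance.
#'
#' @param alpha1,alpha2,alpha3 Means of the latent intercept, latent slope and
#'   mediator (defaults 0).
#' @param gamma2 Effect of the baseline covariate on the latent intercept
#'   (default 0.2).
#' @param lambda Mediator-to-outcome loading. The indirect effect
#'   `lambda * gamma1` is split by fixing `lambda` and solving for `gamma1`,
#'   since only their product is identified by the total effect (default 1).
#' @param psi 2x2 covariance matrix of the latent intercept and slope
#'   (default `diag(c(0.5, 0.05))`).
#' @param theta Mediator residual variance. Defaults to 0.15 for probit
#'   scenarios and 0.17 for logit scenarios (resolved when the link is known),
#'   so that with `lambda = 1` the attenuation factor of the mediator-excluded
#'   mixed model is about 7% (probit) and 3% (logit).
#'
#' @return A list of class `"medtotal_nuisance"`.
#' @export
nuisance_config <- function(alpha1 = 0, alpha2 = 0, alpha3 = 0,
                            gamma2 = 0.2, lambda = 1,
                            psi = diag(c(0.5, 0.05)), theta = NULL) {
  psi <- as.matrix(psi)
  if (!isTRUE(all.equal(psi, t(psi))) || any(eigen(psi, symmetric = TRUE,
                                                   only.values = TRUE)$values < -1e-10)) {
    abort("`psi` must be a symmetric positive semi-definite 2x2 matrix.")
  }
  if (!is.null(theta) && theta <= 0) abort("`theta` must be > 0.")
  if (lambda == 0) abort("`lambda` must be non-zero (it carries the indirect effect).")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 gamma2 = gamma2, lambda = lambda, psi = psi, theta = theta),
            class = "medtotal_nuisance")
}

default_theta <- function(link) if (link == "probit") 0.15 else 0.17

#' Full parameter set of the generative model
#'
#' The latent-growth SEM for a repeated binary outcome: the latent outcome at
#' time `t` is `U1 + t U2 + lambda M + kappa z + e`, with `U1 = alpha1 +
#' gamma2 w + zeta1`, `U2 = alpha2 + zeta2`, mediator `M = alpha3 + gamma1 z +
#' zeta_m`, `cov(zeta1, zeta2) = psi`, `zeta_m ~ N(0, theta)` and `e` standard
#' normal (probit) or standard logistic (logit). The observed outcome is the
#' indicator that the latent outcome exceeds zero.
#'
#' @param link `"probit"` or `"logit"`.
#' @param kappa Direct predictor-to-outcome path.
#' @param gamma1 Predictor-to-mediator path.
#' @param lambda Mediator-to-outcome loading.
#' @param alpha1,alpha2,alpha3,gamma2,psi,theta See [nuisance_config()].
#'
#' @return A list of class `"medtotal_params"`.
#' @seealso [make_scenario()] to build one from a target total effect.
#' @export
true_params <- function(link = c("probit", "logit"), kappa, gamma1, lambda = 1,
                        alpha1 = 0, alpha2 = 0, alpha3 = 0, gamma2 = 0.2,
                        psi = diag(c(0.5, 0.05)), theta = NULL) {
  link <- match.arg(link)
  if (is.null(theta)) theta <- default_theta(link)
  nu <- nuisance_config(alpha1, alpha2, alpha3, gamma2, lambda, psi, theta)
  out <- c(list(link = link, kappa = kappa, gamma1 = gamma1), unclass(nu))
  if (!is.finite(out$lambda * out$gamma1 + out$kappa)) {
    abort("total effect lambda * gamma1 + kappa must be finite.")
  }
  structure(out, class = "medtotal_params")
}

#' Total effect implied by a parameter set
#'
#' The sum of the direct path `kappa` and the indirect path
#' `lambda * gamma1`, on the scale that conditions on the mediator.
#'
#' @param params A [true_params()] object.
#' @return A single number.
#' @export
total_effect <- function(params) {
  stopifnot(inherits(params, "medtotal_params"))
  params$lambda * params$gamma1 + params$kappa
}

#' Build the parameter set for a simulation scenario
#'
#' Splits a target total effect into direct (`kappa`) and indirect
#' (`lambda * gamma1`) components. With an `"equal"` distribution each
#' component is half of the total; `"direct"` (`"indirect"`) assigns
#' `direct_fraction` of the total to the direct (indirect) component.
#'
#' @param link `"probit"` or `"logit"`.
#' @param total_effect Target total effect; must be non-zero.
#' @param distribution One of `"equal"`, `"direct"`, `"indirect"`.
#' @param nuisance A [nuisance_config()] object.
#' @param direct_fraction Share of the total effect given to the dominant
#'   component for the `"direct"`/`"indirect"` distributions; must lie in
#'   (0.5, 1). Default 0.75.
#'
#' @return A [true_params()] object whose implied [total_effect()] equals
#'   `total_effect`.
#' @examples
#' p <- make_scenario("probit", 0.3, "equal")
#' c(p$kappa, p$lambda * p$gamma1)  # 0.15, 0.15
#' @export
make_scenario <- function(link = c("probit", "logit"), total_effect,
                          distribution = c("equal", "direct", "indirect"),
                          nuisance = nuisance_config(),
                          direct_fraction = 0.75) {
  link <- match.arg(link)
  distribution <- match.arg(distribution)
  if (!is.numeric(total_effect) || total_effect == 0) {
    abort("`total_effect` must be non-zero; use a near-zero override for null scenarios.")
  }
  if (direct_fraction <= 0.5 || direct_fraction >= 1) {
    abort("`direct_fraction` must lie strictly between 0.5 and 1.")
  }
  frac <- switch(distribution,
                 equal = 0.5,
                 direct = direct_fraction,
                 indirect = 1 - direct_fraction)
  kappa <- frac * total_effect
  indirect <- total_effect - kappa
  theta <- nuisance$theta %||% default_theta(link)
  true_params(link = link, kappa = kappa,
              gamma1 = indirect / nuisance$lambda, lambda = nuisance$lambda,
              alpha1 = nuisance$alpha1, alpha2 = nuisance$alpha2,
              alpha3 = nuisance$alpha3, gamma2 = nuisance$gamma2,
              psi = nuisance$psi, theta = theta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.medtotal_params <- function(x, ...) {
  cat("<medtotal_params> link =", x$link, "\n")
  cat(sprintf("  direct kappa = %.4g, indirect lambda*gamma1 = %.4g, total = %.4g\n",
              x$kappa, x$lambda * x$gamma1, total_effect(x)))
  cat(sprintf("  lambda = %.4g, theta = %.4g, gamma2 = %.4g, alphas = (%.3g, %.3g, %.3g)\n",
              x$lambda, x$theta, x$gamma2, x$alpha1, x$alpha2, x$alpha3))
  cat("  psi =", paste(signif(x$psi, 4), collapse = " "), "\n")
  invisible(x)
}
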