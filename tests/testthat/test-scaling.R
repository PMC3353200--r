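test_that("scale factor analytics hold", {
  expect_equal(scale_factor("probit", 0, 3), 1)
  expect_equal(scale_factor("logit", 0, 3), 1)
  expect_equal(scale_factor("probit", 1, 1), sqrt(2), tolerance = 1e-12)
  expect_equal(scale_factor("probit", 1, 1), 1.414214, tolerance = 1e-6)
  expect_equal(scale_factor("logit", 1, pi^2 / 3), sqrt(2), tolerance = 1e-12)
  # monotone in |lambda| and theta; logit factor below probit for equal lambda^2 theta
  lt <- expand.grid(l = c(0.5, 1, 2), th = c(0.1, 0.5, 1))
  f_probit <- mapply(function(l, th) scale_factor("probit", l, th), lt$l, lt$th)
  f_logit <- mapply(function(l, th) scale_factor("logit", l, th), lt$l, lt$th)
  expect_true(all(f_probit >= 1) && all(f_logit >= 1))
  expect_true(all(f_logit < f_probit))
  expect_true(all(diff(sapply(c(0.1, 0.3, 0.9), function(th)
    scale_factor("probit", 1, th))) > 0))
  expect_error(scale_factor("probit", 1, -0.1), "non-negative")
})

make_mock_fit <- function(beta, vcov_beta, link = "probit",
                          include_mediator = FALSE) {
  terms <- c("(Intercept)", "w", "t", "z", if (include_mediator) "M")
  dimnames(vcov_beta) <- list(terms, terms)
  structure(list(beta = setNames(beta, terms), vcov_beta = vcov_beta,
                 spec = glmm_spec(link, include_mediator), converged = TRUE),
            class = "medtotal_nlmm")
}

test_that("rescaling multiplies estimate and SE by the scale factor", {
  fit <- make_mock_fit(c(0, 0.2, 0, 0.35), diag(c(1, 1, 1, 0.1)^2))
  r <- rescale_total_effect(fit, lambda = 1, theta = 0.15)
  expect_equal(r$estimate, 0.35 * sqrt(1.15), tolerance = 1e-12)
  expect_equal(r$estimate, 0.375333, tolerance = 1e-6)
  expect_equal(r$se, 0.1 * sqrt(1.15), tolerance = 1e-12)
  expect_equal(r$scale, "conditional_on_mediator")
  # round trip back to the raw coefficient
  expect_equal(r$estimate / scale_factor("probit", 1, 0.15),
               unname(fit$beta["z"]), tolerance = 1e-12)
  # lambda = 0 leaves the fit untouched
  r0 <- rescale_total_effect(fit, 0, 0.15)
  expect_equal(r0$estimate, 0.35)
  expect_equal(r0$se, 0.1)
  # CI and p are Wald
  expect_equal(r$ci_low, r$estimate - qnorm(0.975) * r$se)
  expect_equal(r$p_value, 2 * pnorm(-abs(r$estimate / r$se)))
})

test_that("estimated-mode rescaling propagates scale-factor uncertainty", {
  fit <- make_mock_fit(c(0, 0.2, 0, 0.35), diag(c(1, 1, 1, 0.1)^2))
  vc <- diag(c(0.05^2, 0.02^2))
  r <- rescale_total_effect(fit, 1, 0.15, lam_theta_vcov = vc)
  expect_equal(r$method, "nlmm_scaled_estimated")
  expect_gt(r$se, 0.1 * sqrt(1.15))
  # Monte-Carlo delta-method oracle: simulate (b3, lambda, theta)
  set.seed(1)
  b3 <- rnorm(2e5, 0.35, 0.1)
  lam <- rnorm(2e5, 1, 0.05)
  th <- rnorm(2e5, 0.15, 0.02)
  sim_sd <- sd(b3 * sqrt(1 + lam^2 * th))
  expect_equal(r$se, sim_sd, tolerance = 0.01)
})

test_that("product of coefficients combines paths with delta-method SE", {
  Vb <- diag(c(1, 1, 1, 0.05, 0.04)^2)
  Vb[4, 5] <- Vb[5, 4] <- 0.0004
  fit <- make_mock_fit(c(0, 0.2, 0, 0.15, 0.3), Vb, include_mediator = TRUE)
  med <- structure(list(alpha0 = 0, alpha1 = 0.5,
                        vcov = matrix(c(0.001, 0, 0, 0.03^2), 2,
                                      dimnames = list(c("alpha0", "alpha1"),
                                                      c("alpha0", "alpha1"))),
                        theta_hat = 0.15, theta_se = 0.01),
                   class = "medtotal_medlm")
  r <- product_of_coefficients(fit, med)
  expect_equal(r$estimate, 0.15 + 0.5 * 0.3)
  expect_equal(r$se^2,
               0.05^2 + 0.5^2 * 0.04^2 + 2 * 0.5 * 0.0004 + 0.3^2 * 0.03^2,
               tolerance = 1e-12)
  # Monte-Carlo oracle for the variance formula
  set.seed(2)
  bz <- mvtnorm::rmvnorm(2e5, c(0.15, 0.3),
                         matrix(c(0.05^2, 0.0004, 0.0004, 0.04^2), 2))
  a1 <- rnorm(2e5, 0.5, 0.03)
  expect_equal(r$se, sd(bz[, 1] + a1 * bz[, 2]), tolerance = 0.01)
  # degenerate: no mediator path
  fit0 <- make_mock_fit(c(0, 0.2, 0, 0.15, 0), Vb, include_mediator = TRUE)
  r0 <- product_of_coefficients(fit0, med)
  expect_equal(r0$estimate, 0.15)
})

test_that("scale-mismatch misuse is rejected", {
  fit_excl <- make_mock_fit(c(0, 0.2, 0, 0.35), diag(4))
  fit_incl <- make_mock_fit(c(0, 0.2, 0, 0.15, 0.3), diag(5),
                            include_mediator = TRUE)
  med <- structure(list(alpha1 = 0.5, vcov = diag(2)), class = "medtotal_medlm")
  expect_error(rescale_total_effect(fit_incl, 1, 0.15), "exclude")
  expect_error(product_of_coefficients(fit_excl, med), "include")
  expect_error(unscaled_total_effect(fit_incl), "exclude")
})

test_that("the mediator-excluded target divides the total effect by the factor", {
  p <- make_scenario("probit", 0.3, "equal", nuisance_config(theta = 0.15))
  expect_equal(as.numeric(unscaled_truth("probit", p)), 0.3 / sqrt(1.15),
               tolerance = 1e-12)
  expect_equal(as.numeric(unscaled_truth("probit", p)), 0.279751,
               tolerance = 2e-6)
  expect_false(attr(unscaled_truth("probit", p), "approximate"))
  pl <- make_scenario("logit", 0.3, "equal")
  expect_true(attr(unscaled_truth("logit", pl), "approximate"))
  p0 <- true_params("probit", kappa = 0.2, gamma1 = 0.4, lambda = 1e-12)
  expect_equal(as.numeric(unscaled_truth("probit", p0)), 0.2, tolerance = 1e-9)
})
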