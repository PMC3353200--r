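test_that("adaptive quadrature matches brute-force integration on tiny cohorts", {
  p <- probit_equal_params()
  d <- generate_dataset(p, study_design(5), seed = 3)
  beta <- c(0.1, 0.2, -0.05, 0.25)
  re_cov <- matrix(c(0.5, 0.05, 0.05, 0.06), 2)
  for (link in c("probit", "logit")) {
    bf <- brute_loglik(d, beta, re_cov, link)
    ag <- marginal_loglik(d, beta, re_cov, link, nodes = 15)
    expect_lt(abs(ag - bf), 1e-6)
  }
})

test_that("zero random-effect covariance collapses to the plain GLM log-likelihood", {
  d <- generate_dataset(logit_equal_params(), study_design(30), seed = 4)
  beta <- c(-0.2, 0.1, 0.05, 0.3)
  for (link in c("probit", "logit")) {
    expect_equal(marginal_loglik(d, beta, matrix(0, 2, 2), link),
                 plain_glm_loglik(d, beta, link), tolerance = 1e-10)
  }
  expect_error(marginal_loglik(d, beta, matrix(c(1, 2, 2, 1), 2), "logit"),
               "positive definite")
})

test_that("the quadrature is converged at the default node count", {
  d <- generate_dataset(probit_equal_params(), study_design(100), seed = 10)
  beta <- c(0, 0.2, 0, 0.28)
  re_cov <- matrix(c(0.43, 0, 0, 0.044), 2)
  for (link in c("probit", "logit")) {
    l15 <- marginal_loglik(d, beta, re_cov, link, nodes = 15)
    l40 <- marginal_loglik(d, beta, re_cov, link, nodes = 40)
    expect_lt(abs(l15 - l40), 1e-4)
  }
})

test_that("with no random effects and no mediation the NLMM matches a plain GLM", {
  p <- true_params("probit", kappa = 0.3, gamma1 = 0, lambda = 1e-6,
                   psi = matrix(0, 2, 2), theta = 0.15)
  d <- cached_dataset("psi0_n2000", function()
    generate_dataset(p, study_design(2000), seed = 31))
  fit <- fit_nlmm(d, "probit", nodes = 7)
  ref <- glm(Y ~ w + t + z, binomial("probit"), data = d)
  expect_lt(max(abs(fit$beta - coef(ref))), 0.02)
  se <- sqrt(fit$vcov_beta["z", "z"])
  expect_lt(abs(fit$beta["z"] - 0.3), 3 * se)
})

test_that("the mediator-included fit recovers the unattenuated structural paths", {
  p <- probit_equal_params()
  d <- cached_dataset("probit_n5000_seed7", function()
    generate_dataset(p, study_design(5000), seed = 7))
  fit <- fit_nlmm(d, "probit", include_mediator = TRUE, nodes = 7)
  expect_true(fit$converged)
  se_z <- sqrt(fit$vcov_beta["z", "z"])
  se_M <- sqrt(fit$vcov_beta["M", "M"])
  expect_lt(abs(fit$beta["z"] - p$kappa), 3 * se_z)
  expect_lt(abs(fit$beta["M"] - p$lambda), 3 * se_M)
})

test_that("logit and probit coefficients keep the usual scale relationship", {
  d <- cached_dataset("probit_n5000_seed7", function()
    generate_dataset(probit_equal_params(), study_design(5000), seed = 7))
  fp <- fit_nlmm(d, "probit", nodes = 7)
  fl <- fit_nlmm(d, "logit", nodes = 7)
  ratio <- fl$beta[c("w", "z")] / fp$beta[c("w", "z")]
  expect_true(all(ratio > 1.4 & ratio < 2.0))
})

test_that("an established Laplace-approximation fitter lands near our estimates", {
  skip_if_not_installed("lme4")
  d <- generate_dataset(logit_equal_params(), study_design(400), seed = 17)
  ours <- fit_nlmm(d, "logit", nodes = 7)
  ref <- lme4::glmer(Y ~ w + t + z + (1 + t | subject_id), data = d,
                     family = binomial("logit"))
  # Laplace vs adaptive quadrature: agreement is approximate by construction
  expect_lt(max(abs(ours$beta - lme4::fixef(ref))), 0.05)
})

test_that("fitting degenerate inputs fails loudly", {
  d <- generate_dataset(probit_equal_params(), study_design(30), seed = 2)
  expect_error(fit_nlmm(d[0, ], "probit"), "empty")
  d_const <- dplyr::mutate(d, Y = 1L)
  expect_error(fit_nlmm(d_const, "probit"), "separation|constant")
  d_one <- dplyr::filter(d, subject_id == 1)
  expect_error(fit_nlmm(d_one, "probit"), "2 subjects")
})

test_that("the mediator linear model estimates path and residual variance", {
  d_exact <- tibble::tibble(M = rep(0:1, 20), z = rep(0:1, 20),
                            subject_id = rep(1:20, each = 2))
  f <- fit_mediator_lm(d_exact)
  expect_equal(f$alpha1, 1)
  expect_lt(f$theta_hat, 1e-10)

  p <- probit_equal_params()
  d <- cached_dataset("probit_n5000_seed7", function()
    generate_dataset(p, study_design(5000), seed = 7))
  f2 <- fit_mediator_lm(d)
  expect_lt(abs(f2$alpha1 - p$gamma1), 3 * sqrt(f2$vcov["alpha1", "alpha1"]))
  expect_lt(abs(f2$theta_hat - p$theta), 3 * f2$theta_se)
  expect_error(fit_mediator_lm(dplyr::mutate(d, z = 1)), "rank deficient")
})

test_that("tidy and glance return well-formed summaries", {
  d <- generate_dataset(logit_equal_params(), study_design(80), seed = 19)
  fit <- fit_nlmm(d, "logit", nodes = 7)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term, c("(Intercept)", "w", "t", "z"))
  gl <- glance(fit)
  expect_true(is.logical(gl$converged))
  tm <- tidy(fit_mediator_lm(d))
  expect_equal(tm$term, c("alpha0", "alpha1", "theta"))
})
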