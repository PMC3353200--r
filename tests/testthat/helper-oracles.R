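# Independent oracles, written in plain R against the model definitions and
# kept deliberately separate from the package's C++ likelihood path.

# Marginal log-likelihood by brute-force 2-D trapezoidal integration of the
# random effects over [-8 sd, 8 sd]^2. The integrand decays like a Gaussian,
# so the trapezoid rule converges spectrally in the number of grid points.
brute_loglik <- function(data, beta, re_cov, link, n_grid = 401) {
  data <- data[order(data$subject_id, data$t), ]
  s1 <- sqrt(re_cov[1, 1]); s2 <- sqrt(re_cov[2, 2])
  g1 <- seq(-8 * s1, 8 * s1, length.out = n_grid)
  g2 <- seq(-8 * s2, 8 * s2, length.out = n_grid)
  h1 <- diff(g1)[1]; h2 <- diff(g2)[1]
  gr <- as.matrix(expand.grid(b1 = g1, b2 = g2))
  dens <- mvtnorm::dmvnorm(gr, sigma = re_cov)
  total <- 0
  for (id in unique(data$subject_id)) {
    di <- data[data$subject_id == id, ]
    eta0 <- beta[1] + beta[2] * di$w + beta[3] * di$t + beta[4] * di$z
    if (length(beta) == 5) eta0 <- eta0 + beta[5] * di$M
    lik <- rep(1, nrow(gr))
    for (j in seq_len(nrow(di))) {
      eta <- eta0[j] + gr[, 1] + gr[, 2] * di$t[j]
      pj <- if (link == "probit") pnorm(eta) else plogis(eta)
      lik <- lik * (if (di$Y[j] == 1) pj else 1 - pj)
    }
    total <- total + log(sum(lik * dens) * h1 * h2)
  }
  total
}

# Ordinary binary-regression log-likelihood (no random effects), plain R.
plain_glm_loglik <- function(data, beta, link) {
  eta <- beta[1] + beta[2] * data$w + beta[3] * data$t + beta[4] * data$z
  p <- if (link == "probit") pnorm(eta) else plogis(eta)
  sum(data$Y * log(p) + (1 - data$Y) * log(1 - p))
}

# A small shared dataset cache so expensive generated cohorts are built once
# per test run.
.fixture_cache <- new.env(parent = emptyenv())
cached_dataset <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

probit_equal_params <- function() make_scenario("probit", 0.3, "equal")
logit_equal_params <- function() make_scenario("logit", 0.3, "equal")
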