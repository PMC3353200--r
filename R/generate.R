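#' Study design for simulated cohorts
#'
#' @param n_subjects Number of subjects.
#' @param n_times Measurements per subject (default 6).
#' @param time_values Strictly increasing measurement times shared by all
#'   subjects (default `0:(n_times - 1)`, i.e. equally spaced).
#' @param z_prevalence Probability that the repeated binary predictor is 1 at
#'   any visit (default 0.5); draws are independent across visits.
#' @param w_mean,w_sd Mean and SD of the normal baseline covariate
#'   (defaults 0 and 1).
#'
#' @return A list of class `"medtotal_design"`.
#' @export
study_design <- function(n_subjects, n_times = 6,
                         time_values = seq_len(n_times) - 1,
                         z_prevalence = 0.5, w_mean = 0, w_sd = 1) {
  if (n_subjects < 1) abort("`n_subjects` must be positive.")
  if (length(time_values) != n_times) {
    abort("`time_values` must have length `n_times`.")
  }
  if (any(diff(time_values) <= 0)) abort("`time_values` must be strictly increasing.")
  if (z_prevalence <= 0 || z_prevalence >= 1) abort("`z_prevalence` must be in (0, 1).")
  if (w_sd < 0) abort("`w_sd` must be non-negative.")
  structure(list(n_subjects = as.integer(n_subjects), n_times = as.integer(n_times),
                 time_values = as.numeric(time_values),
                 z_prevalence = z_prevalence, w_mean = w_mean, w_sd = w_sd),
            class = "medtotal_design")
}

# PSD-safe matrix square root, tolerating singular psi (e.g. no random slope).
psi_sqrt <- function(psi) {
  e <- eigen(psi, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = 2) %*% t(e$vectors)
}

#' Simulate a longitudinal mediated binary dataset
#'
#' Draws one cohort from the latent-growth SEM described in [true_params()]:
#' per subject a baseline covariate `w`, growth-factor residuals
#' `(zeta1, zeta2)` with covariance `psi`, and per visit an independent binary
#' predictor `z`, a mediator `M = alpha3 + gamma1 z + zeta_m`, and a latent
#' outcome `Ystar = U1 + t U2 + lambda M + kappa z + e`, dichotomised at zero.
#' Probit scenarios use standard-normal `e`; logit scenarios use standard
#' logistic `e` obtained by inverse-CDF transform of a uniform draw.
#'
#' @param params A [true_params()] object.
#' @param design A [study_design()] object.
#' @param seed Integer seed; the same seed always reproduces the same dataset.
#' @param keep_latent Keep the latent outcome as a `Ystar` column
#'   (default `TRUE`; useful for diagnostics and tests).
#'
#' @return A tibble in long format with columns `subject_id`, `time_index`
#'   (0-based), `t`, `w`, `z`, `M`, `Y` and optionally `Ystar`.
#' @examples
#' d <- generate_dataset(make_scenario("probit", 0.3, "equal"),
#'                       study_design(50), seed = 1)
#' dplyr::count(d, Y)
#' @export
generate_dataset <- function(params, design, seed, keep_latent = TRUE) {
  stopifnot(inherits(params, "medtotal_params"), inherits(design, "medtotal_design"))
  if (missing(seed) || !is.numeric(seed)) abort("an integer `seed` is required.")
  n <- design$n_subjects
  J <- design$n_times
  tv <- design$time_values

  withr::with_seed(as.integer(seed), {
    w <- rnorm(n, design$w_mean, design$w_sd)
    z <- matrix(rbinom(n * J, 1, design$z_prevalence), n, J)
    zeta12 <- matrix(rnorm(2 * n), n, 2) %*% psi_sqrt(params$psi)
    zeta_m <- matrix(rnorm(n * J, 0, sqrt(params$theta)), n, J)
    eps <- if (params$link == "probit") {
      matrix(rnorm(n * J), n, J)
    } else {
      matrix(qlogis(runif(n * J)), n, J)
    }
  })

  M <- params$alpha3 + params$gamma1 * z + zeta_m
  U1 <- params$alpha1 + params$gamma2 * w + zeta12[, 1]
  U2 <- params$alpha2 + zeta12[, 2]
  Ystar <- U1 + outer(U2, tv) + params$lambda * M + params$kappa * z + eps

  out <- tibble(
    subject_id = rep(seq_len(n), each = J),
    time_index = rep(seq_len(J) - 1L, times = n),
    t = rep(tv, times = n),
    w = rep(w, each = J),
    z = as.integer(t(z)),
    M = as.numeric(t(M)),
    Y = as.integer(t(Ystar) > 0),
    Ystar = as.numeric(t(Ystar))
  )
  if (!keep_latent) out$Ystar <- NULL
  out
}

#' Closed-form marginal success probability under the probit model
#'
#' With normal growth residuals, mediator residual and measurement error, the
#' latent outcome is normal given `(w, z, t)`, so the marginal probability of
#' a positive outcome has an exact probit expression:
#' `pnorm(omega / sqrt(1 + lambda^2 theta + psi11 + 2 t psi12 + t^2 psi22))`
#' with `omega = alpha1 + lambda alpha3 + gamma2 w + alpha2 t +
#' (kappa + lambda gamma1) z`. Used as the generator's oracle in tests.
#'
#' @param params A probit [true_params()] object.
#' @param w,z,t Covariate value, predictor value and time.
#' @return Probability of observing `Y = 1`.
#' @export
probit_marginal_prob <- function(params, w, z, t) {
  stopifnot(inherits(params, "medtotal_params"))
  if (params$link != "probit") abort("closed form available for the probit link only.")
  omega <- (params$alpha1 + params$lambda * params$alpha3) + params$gamma2 * w +
    params$alpha2 * t + (params$kappa + params$lambda * params$gamma1) * z
  v <- 1 + params$lambda^2 * params$theta +
    params$psi[1, 1] + 2 * t * params$psi[1, 2] + t^2 * params$psi[2, 2]
  pnorm(omega / sqrt(v))
}
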