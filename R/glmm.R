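#' Model specification for the binary-outcome mixed model
#'
#' Fixed effects are an intercept, the baseline covariate `w`, time `t`, the
#' binary predictor `z` and, when `include_mediator` is `TRUE`, the mediator
#' `M`. Random effects are a correlated subject intercept and slope on `t`.
#'
#' @param link `"probit"` or `"logit"`.
#' @param include_mediator Include `M` among the fixed effects? Excluding it
#'   makes the predictor coefficient a total (direct plus indirect) effect on
#'   a scale marginal to the mediator residual.
#' @param nodes Gauss-Hermite nodes per random-effect dimension (default 15).
#' @return A list of class `"medtotal_glmm_spec"`.
#' @export
glmm_spec <- function(link = c("probit", "logit"), include_mediator = FALSE,
                      nodes = 15) {
  link <- match.arg(link)
  if (nodes < 2) abort("`nodes` must be at least 2.")
  terms <- c("(Intercept)", "w", "t", "z", if (include_mediator) "M")
  structure(list(link = link, include_mediator = include_mediator,
                 nodes = as.integer(nodes), terms = terms),
            class = "medtotal_glmm_spec")
}

link_code <- function(link) if (link == "probit") 0L else 1L

# Long data -> matrices for the C++ likelihood. Rows are re-sorted by
# (subject_id, t); subjects may have unequal numbers of visits.
nlmm_data_parts <- function(data, spec) {
  need <- c("subject_id", "t", "w", "z", "Y", if (spec$include_mediator) "M")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("`data` lacks column(s): ", paste(miss, collapse = ", ")))
  if (nrow(data) == 0) abort("`data` is empty.")
  data <- data[order(data$subject_id, data$t), , drop = FALSE]
  X <- cbind(1, data$w, data$t, data$z)
  if (spec$include_mediator) X <- cbind(X, data$M)
  colnames(X) <- spec$terms
  runs <- rle(data$subject_id)
  len <- runs$lengths
  list(X = X, t = as.numeric(data$t), y = as.numeric(data$Y),
       sub_start = as.integer(cumsum(len) - len), sub_len = as.integer(len),
       n_subjects = length(len))
}

# log-Cholesky transform of a 2x2 covariance and its inverse
lpar_from_cov <- function(re_cov) {
  L <- t(chol(re_cov))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}
cov_from_lpar <- function(lpar) {
  L <- matrix(c(exp(lpar[1]), lpar[2], 0, exp(lpar[3])), 2, 2)
  L %*% t(L)
}

#' Marginal log-likelihood of the binary mixed model
#'
#' Integrates the conditional Bernoulli likelihood over the bivariate normal
#' random intercept and slope by adaptive Gauss-Hermite quadrature: per
#' subject the integrand is re-centred at the posterior mode of the random
#' effects and re-scaled by the curvature there, then evaluated on a tensor
#' grid of `nodes^2` Gauss-Hermite points. A zero covariance collapses to the
#' ordinary probit/logit regression log-likelihood.
#'
#' @param data Long-format data with columns `subject_id`, `t`, `w`, `z`, `Y`
#'   and, if `include_mediator`, `M`.
#' @param beta Fixed-effect coefficients in the order of `glmm_spec()$terms`.
#' @param re_cov 2x2 random-effect covariance (positive definite, or exactly
#'   zero for the degenerate case).
#' @param link,include_mediator,nodes See [glmm_spec()].
#' @return The marginal log-likelihood (a single number).
#' @export
marginal_loglik <- function(data, beta, re_cov, link = c("probit", "logit"),
                            include_mediator = FALSE, nodes = 15) {
  link <- match.arg(link)
  spec <- glmm_spec(link, include_mediator, nodes)
  parts <- nlmm_data_parts(data, spec)
  if (length(beta) != ncol(parts$X)) {
    abort(sprintf("`beta` must have length %d for this specification.", ncol(parts$X)))
  }
  re_cov <- as.matrix(re_cov)
  if (!isTRUE(all.equal(re_cov, t(re_cov), tolerance = 1e-8))) {
    abort("`re_cov` must be symmetric.")
  }
  if (all(abs(re_cov) < 1e-12)) {
    return(glm_loglik_cpp(beta, parts$X, parts$y, link_code(link)))
  }
  ev <- eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) abort("`re_cov` must be positive definite (or exactly zero).")
  gh <- statmod::gauss.quad(nodes, kind = "hermite")
  res <- nlmm_objective_cpp(c(beta, lpar_from_cov(re_cov)), parts$X, parts$t,
                            parts$y, parts$sub_start, parts$sub_len,
                            link_code(link), gh$nodes, gh$weights, FALSE, FALSE)
  res$loglik
}

# Objective closures over the C++ kernel, with memoisation of the last
# evaluated parameter vector (optim calls fn and gr back to back).
nlmm_objective <- function(parts, link, nodes) {
  gh <- statmod::gauss.quad(nodes, kind = "hermite")
  last <- new.env(parent = emptyenv())
  eval_at <- function(par, hess = FALSE) {
    if (!is.null(last$par) && identical(par, last$par) &&
        (!hess || !is.null(last$res$hessian))) return(last$res)
    res <- nlmm_objective_cpp(par, parts$X, parts$t, parts$y, parts$sub_start,
                              parts$sub_len, link_code(link), gh$nodes,
                              gh$weights, TRUE, hess)
    last$par <- par
    last$res <- res
    res
  }
  list(fn = function(par) -eval_at(par)$loglik,
       gr = function(par) -eval_at(par)$gradient,
       eval = eval_at)
}

# Maximise the marginal likelihood by damped Newton with the analytic
# observed information; bounds keep the log-Cholesky diagonals away from
# -Inf when a random-effect variance is genuinely zero.
# Remaining achievable log-likelihood gain (Newton decrement), measured only
# along identifiable directions: eigendirections of the observed information
# whose eigenvalue is a vanishing fraction of the largest correspond to
# boundary-degenerate variance parameters (e.g. correlation pinned at +-1)
# and carry no information about the estimates.
newton_decrement <- function(g, H, ridge_frac = 1e-6) {
  e <- eigen(H, symmetric = TRUE)
  keep <- e$values > ridge_frac * max(e$values, 0) & e$values > 0
  if (!any(keep)) return(Inf)
  gp <- drop(crossprod(e$vectors[, keep, drop = FALSE], g))
  sum(gp^2 / (2 * e$values[keep]))
}

newton_maximize <- function(obj, par0, lower, grad_tol, max_iter = 80) {
  par <- pmax(par0, lower)
  ev <- try(obj$eval(par, hess = TRUE), silent = TRUE)
  if (inherits(ev, "try-error")) return(list(ok = FALSE, par = par))
  for (it in seq_len(max_iter)) {
    g <- ev$gradient
    H <- -ev$hessian
    act <- par <= lower + 1e-7 & g < 0   # gradient pushes into the bound
    if (max(abs(g[!act])) < grad_tol ||
        (it > 1 && newton_decrement(g, H) < 1e-8)) {
      return(list(ok = TRUE, par = par, ev = ev, converged = TRUE, H = H))
    }
    ridge <- 0
    repeat {
      ch <- try(chol(H + diag(ridge, nrow(H))), silent = TRUE)
      if (!inherits(ch, "try-error")) break
      ridge <- if (ridge == 0) 1e-4 * max(diag(H), 1) else ridge * 10
      if (ridge > 1e8) return(list(ok = FALSE, par = par, ev = ev, H = H))
    }
    step <- backsolve(ch, forwardsolve(t(ch), g))
    # accept tiny likelihood decreases: the quadrature score's zero (the
    # reported estimate) can sit a hair off the quadrature objective's max
    sc <- 1
    repeat {
      cand <- pmax(par + sc * step, lower)
      ev_new <- try(obj$eval(cand, hess = TRUE), silent = TRUE)
      if (!inherits(ev_new, "try-error") && is.finite(ev_new$loglik) &&
          ev_new$loglik >= ev$loglik - 1e-6 * max(1, abs(ev$loglik) * 1e-3)) break
      sc <- sc / 2
      if (sc < 1e-4) return(list(ok = TRUE, par = par, ev = ev,
                                 converged = newton_decrement(g, H) < 1e-6,
                                 H = H))
    }
    par <- cand; ev <- ev_new
  }
  g <- ev$gradient; H <- -ev$hessian
  list(ok = TRUE, par = par, ev = ev,
       converged = newton_decrement(g, H) < 1e-6, H = H)
}

#' Fit the binary-outcome mixed model by maximum likelihood
#'
#' Maximises the adaptive Gauss-Hermite marginal likelihood over the fixed
#' effects and the log-Cholesky factor of the random-effect covariance, by
#' quasi-Newton iterations followed by Newton polishing with a numerical
#' Hessian. Standard errors come from the inverse observed information.
#'
#' @inheritParams marginal_loglik
#' @param start Optional list with elements `beta` and `re_cov` to override
#'   the default starting values (an ordinary GLM fit and a modest diagonal
#'   covariance).
#' @param grad_tol Convergence declared when the largest absolute score (over
#'   parameters away from their bounds) falls below this (default `1e-5`), or
#'   when the Newton decrement - the achievable log-likelihood gain along
#'   identifiable directions - is below `1e-8`; the second clause recognises
#'   maxima on the boundary of the variance space (a random-effect
#'   correlation pinned at +-1), where a component of the raw score need not
#'   vanish.
#' @return An object of class `"medtotal_nlmm"` with elements `beta`,
#'   `re_cov`, `vcov_beta`, `loglik`, `converged`, `max_grad`, `n_subjects`
#'   and `spec`. Non-convergence is reported through `converged`, never by
#'   an error, so simulation code can count and drop such fits.
#' @examples
#' d <- generate_dataset(make_scenario("probit", 0.3, "equal"),
#'                       study_design(150), seed = 42)
#' fit <- fit_nlmm(d, link = "probit")
#' tidy(fit)
#' @export
fit_nlmm <- function(data, link = c("probit", "logit"), include_mediator = FALSE,
                     nodes = 15, start = NULL, grad_tol = 1e-5) {
  link <- match.arg(link)
  spec <- glmm_spec(link, include_mediator, nodes)
  parts <- nlmm_data_parts(data, spec)
  if (parts$n_subjects < 2) abort("at least 2 subjects are required.")
  if (length(unique(parts$y)) < 2) {
    abort("outcome is constant; the model is not identifiable (complete separation).")
  }
  p <- ncol(parts$X)

  if (is.null(start)) {
    g0 <- suppressWarnings(glm.fit(parts$X, parts$y, family = binomial(link)))
    par0 <- c(g0$coefficients, lpar_from_cov(diag(c(0.3, 0.03))))
  } else {
    par0 <- c(start$beta, lpar_from_cov(start$re_cov))
  }

  obj <- nlmm_objective(parts, link, nodes)
  lower <- c(rep(-Inf, p), log(1e-3), -Inf, log(1e-3))
  res <- newton_maximize(obj, par0, lower, grad_tol)
  if (!res$ok || !isTRUE(res$converged)) {
    # fall back to quasi-Newton from the GLM start, then retry Newton
    opt <- try(optim(par0, obj$fn, obj$gr, method = "L-BFGS-B", lower = lower,
                     control = list(maxit = 300)), silent = TRUE)
    if (!inherits(opt, "try-error")) {
      res2 <- newton_maximize(obj, opt$par, lower, grad_tol)
      if (res2$ok && (!res$ok || res2$ev$loglik >= res$ev$loglik - 1e-8)) res <- res2
    }
  }
  if (!res$ok) abort("numerical failure: the marginal likelihood could not be evaluated.")
  par <- res$par
  g <- res$ev$gradient
  act <- par <= lower + 1e-7 & g < 0
  max_grad <- max(abs(g[!act]))
  converged <- isTRUE(res$converged) && is.finite(max_grad)

  vcov_all <- tryCatch(solve(res$H), error = function(e) matrix(NA_real_, p + 3, p + 3))
  if (!all(is.finite(diag(vcov_all))) || any(diag(vcov_all)[seq_len(p)] <= 0)) {
    converged <- FALSE
  }
  beta <- setNames(par[seq_len(p)], spec$terms)
  vcov_beta <- vcov_all[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcov_beta) <- list(spec$terms, spec$terms)
  structure(list(beta = beta, re_cov = cov_from_lpar(par[p + 1:3]),
                 vcov_beta = vcov_beta,
                 vcov_all = vcov_all, lpar = par[p + 1:3],
                 loglik = res$ev$loglik, converged = converged, max_grad = max_grad,
                 n_subjects = parts$n_subjects, nobs = length(parts$y),
                 spec = spec),
            class = "medtotal_nlmm")
}

#' @export
print.medtotal_nlmm <- function(x, ...) {
  cat(sprintf("<medtotal_nlmm> %s link, mediator %s, %d subjects (%d obs)\n",
              x$spec$link, if (x$spec$include_mediator) "included" else "excluded",
              x$n_subjects, x$nobs))
  cat(sprintf("  logLik %.3f, %s (max |score| %.2g)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$max_grad))
  print(round(rbind(estimate = x$beta,
                    std.error = sqrt(diag(x$vcov_beta))), 4))
  cat("  random-effect covariance:\n")
  print(round(x$re_cov, 4))
  invisible(x)
}

#' @rdname fit_nlmm
#' @param x A fitted `"medtotal_nlmm"` object.
#' @param ... Unused.
#' @export
tidy.medtotal_nlmm <- function(x, ...) {
  se <- sqrt(diag(x$vcov_beta))
  tibble(term = names(x$beta), estimate = unname(x$beta), std.error = se,
         statistic = unname(x$beta) / se,
         p.value = 2 * pnorm(-abs(unname(x$beta) / se)))
}

#' @rdname fit_nlmm
#' @export
glance.medtotal_nlmm <- function(x, ...) {
  tibble(logLik = x$loglik, converged = x$converged, max_grad = x$max_grad,
         n_subjects = x$n_subjects, nobs = x$nobs, link = x$spec$link,
         include_mediator = x$spec$include_mediator,
         re_var_intercept = x$re_cov[1, 1], re_var_slope = x$re_cov[2, 2],
         re_cov_is = x$re_cov[1, 2])
}

#' Maximum-likelihood linear model for the mediator
#'
#' Fits `M = alpha0 + alpha1 z + e` with independent normal errors by least
#' squares; the ML residual variance estimates the mediator residual variance
#' used in the scale factor. Independent errors match the generative model,
#' whose mediator residuals are uncorrelated across visits.
#'
#' @param data Long-format data with columns `M` and `z`.
#' @return An object of class `"medtotal_medlm"` with `alpha0`, `alpha1`,
#'   `theta_hat` (ML residual variance, floored at `1e-12`), `vcov` (2x2, for
#'   the coefficients), `theta_se` and `loglik`.
#' @export
fit_mediator_lm <- function(data) {
  if (!all(c("M", "z") %in% names(data))) abort("`data` needs columns `M` and `z`.")
  z <- as.numeric(data$z); M <- as.numeric(data$M)
  if (length(unique(z)) < 2) {
    abort("`z` is constant: the mediator model is rank deficient.")
  }
  n <- length(M)
  X <- cbind(1, z)
  fit <- lm.fit(X, M)
  theta_hat <- max(sum(fit$residuals^2) / n, 1e-12)  # ML variance
  XtX_inv <- chol2inv(chol(crossprod(X)))
  vc <- theta_hat * XtX_inv
  dimnames(vc) <- list(c("alpha0", "alpha1"), c("alpha0", "alpha1"))
  structure(list(alpha0 = unname(fit$coefficients[1]),
                 alpha1 = unname(fit$coefficients[2]),
                 theta_hat = theta_hat, vcov = vc,
                 theta_se = sqrt(2 * theta_hat^2 / n),
                 loglik = -n / 2 * (log(2 * pi * theta_hat) + 1),
                 nobs = n),
            class = "medtotal_medlm")
}

#' @export
print.medtotal_medlm <- function(x, ...) {
  cat(sprintf("<medtotal_medlm> alpha0 = %.4f, alpha1 = %.4f (SE %.4f), theta = %.4f\n",
              x$alpha0, x$alpha1, sqrt(x$vcov[2, 2]), x$theta_hat))
  invisible(x)
}

#' @rdname fit_mediator_lm
#' @param x A fitted `"medtotal_medlm"` object.
#' @param ... Unused.
#' @export
tidy.medtotal_medlm <- function(x, ...) {
  est <- c(x$alpha0, x$alpha1, x$theta_hat)
  se <- c(sqrt(diag(x$vcov)), x$theta_se)
  tibble(term = c("alpha0", "alpha1", "theta"), estimate = est, std.error = se,
         statistic = est / se, p.value = 2 * pnorm(-abs(est / se)))
}

#' @rdname fit_mediator_lm
#' @export
glance.medtotal_medlm <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$nobs, theta_hat = x$theta_hat)
}
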