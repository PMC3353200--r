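#' Define a Monte-Carlo scenario
#'
#' One cell of the evaluation grid: a link, a cohort size, a total effect and
#' its direct/indirect split, a replication count and a seed. Nuisance
#' parameters and the study design default to the package's documented
#' generative conditions.
#'
#' @param link `"probit"` or `"logit"`.
#' @param n_subjects Subjects per replicate (at least 20).
#' @param total_effect True conditional total effect.
#' @param distribution `"equal"`, `"direct"` or `"indirect"`.
#' @param n_reps Number of replicate datasets (at least 1).
#' @param seed Scenario seed; per-replicate seeds are derived from it by a
#'   counter scheme so serial and parallel runs agree.
#' @param nuisance A [nuisance_config()].
#' @param design Optional [study_design()]; defaults to 6 equally spaced
#'   visits, `z` prevalence 0.5 and a standard-normal baseline covariate.
#' @param direct_fraction Dominant share for unequal splits (default 0.75).
#' @return A list of class `"medtotal_scenario"`.
#' @export
scenario <- function(link, n_subjects, total_effect,
                     distribution = "equal", n_reps = 1000, seed = 1,
                     nuisance = nuisance_config(), design = NULL,
                     direct_fraction = 0.75) {
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  if (n_subjects < 20) abort("`n_subjects` must be at least 20.")
  params <- make_scenario(link, total_effect, distribution, nuisance,
                          direct_fraction)
  if (is.null(design)) design <- study_design(n_subjects)
  design$n_subjects <- as.integer(n_subjects)
  structure(list(link = link, n_subjects = as.integer(n_subjects),
                 total_effect = total_effect, distribution = distribution,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 params = params, design = design),
            class = "medtotal_scenario")
}

# Deterministic per-replicate seed below 2^31, computed in doubles.
replicate_seed <- function(scenario_seed, r) {
  as.integer((as.numeric(scenario_seed) * 100003 + as.numeric(r) * 7919) %%
               2147483647) + 1L
}

all_methods <- c("nlmm_unscaled", "nlmm_scaled_true", "nlmm_scaled_estimated",
                 "sem_ml")

# One replicate -> tibble of effect estimates (rows per requested method)
run_replicate <- function(scn, r, methods, nodes) {
  d <- generate_dataset(scn$params, scn$design, seed = replicate_seed(scn$seed, r),
                        keep_latent = FALSE)
  need0 <- any(methods %in% c("nlmm_unscaled", "nlmm_scaled_true",
                              "nlmm_scaled_estimated"))
  need1 <- any(methods %in% c("nlmm_scaled_estimated", "sem_ml"))
  fit0 <- if (need0) try(fit_nlmm(d, scn$link, FALSE, nodes), silent = TRUE)
  fit1 <- if (need1) try(fit_nlmm(d, scn$link, TRUE, nodes), silent = TRUE)
  med <- if (need1) try(fit_mediator_lm(d), silent = TRUE)
  ok0 <- need0 && !inherits(fit0, "try-error")
  ok1 <- need1 && !inherits(fit1, "try-error") && !inherits(med, "try-error")
  rows <- list()
  if (ok0 && "nlmm_unscaled" %in% methods) {
    rows$u <- dplyr::mutate(unscaled_total_effect(fit0), converged = fit0$converged)
  }
  if (ok0 && "nlmm_scaled_true" %in% methods) {
    rows$st <- dplyr::mutate(
      rescale_total_effect(fit0, scn$params$lambda, scn$params$theta),
      converged = fit0$converged)
  }
  if (ok0 && ok1 && "nlmm_scaled_estimated" %in% methods) {
    vc <- diag(c(fit1$vcov_beta["M", "M"], med$theta_se^2))
    rows$se <- dplyr::mutate(
      rescale_total_effect(fit0, unname(fit1$beta["M"]), med$theta_hat, vc),
      converged = fit0$converged && fit1$converged)
  }
  if (ok1 && "sem_ml" %in% methods) {
    rows$pc <- dplyr::mutate(product_of_coefficients(fit1, med),
                             converged = fit1$converged)
  }
  if (!length(rows)) return(NULL)
  dplyr::mutate(dplyr::bind_rows(rows), replicate = r)
}

#' Run one Monte-Carlo scenario
#'
#' Generates `n_reps` replicate cohorts (seeded deterministically), fits the
#' requested estimators on each, and summarises per method: percent bias of
#' the mean estimate, coverage of nominal 95% Wald intervals, and power of
#' the two-sided Wald test at the 5% level. The truth is the conditional
#' total effect for conditional-scale methods and [unscaled_truth()] for the
#' unscaled estimator. Replicates whose fit did not converge are dropped
#' from all three metrics and counted.
#'
#' @param scn A [scenario()].
#' @param methods Subset of `"nlmm_unscaled"`, `"nlmm_scaled_true"`,
#'   `"nlmm_scaled_estimated"`, `"sem_ml"` (default all four).
#' @param nodes Quadrature nodes per dimension for the replicate fits
#'   (default 7; adaptive quadrature is already accurate at this order, and
#'   replicate fits dominate the harness's run time).
#' @param parallelism Worker processes for replicate fitting (default 1);
#'   results are identical for any value because seeds are per-replicate.
#' @param keep_estimates Attach the per-replicate estimate table as the
#'   `"estimates"` attribute (default `FALSE`).
#' @return A tibble of class `"medtotal_result"`, one row per method, with
#'   columns `method`, `bias_pct`, `coverage_pct`, `power_pct`,
#'   `n_converged`, `mc_se_coverage`, and scenario metadata columns.
#' @export
run_scenario <- function(scn, methods = all_methods, nodes = 7,
                         parallelism = 1, keep_estimates = FALSE) {
  stopifnot(inherits(scn, "medtotal_scenario"))
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  reps <- seq_len(scn$n_reps)
  runs <- if (parallelism > 1) {
    parallel::mclapply(reps, function(r) run_replicate(scn, r, methods, nodes),
                       mc.cores = parallelism, mc.preschedule = TRUE)
  } else {
    lapply(reps, function(r) run_replicate(scn, r, methods, nodes))
  }
  est <- dplyr::bind_rows(runs)
  if (nrow(est) == 0 || sum(est$converged) == 0) {
    abort("no replicate produced a converged fit.")
  }
  truth_cond <- total_effect(scn$params)
  truth_marg <- as.numeric(unscaled_truth(scn$link, scn$params))
  est <- dplyr::mutate(est, truth = ifelse(.data$method == "nlmm_unscaled",
                                           truth_marg, truth_cond))
  out <- est |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      bias_pct = 100 * (mean(.data$estimate) - .data$truth[1]) / .data$truth[1],
      coverage_pct = 100 * mean(.data$ci_low <= .data$truth &
                                  .data$truth <= .data$ci_high),
      power_pct = 100 * mean(.data$p_value < 0.05),
      n_converged = dplyr::n(),
      mean_estimate = mean(.data$estimate),
      mean_se = mean(.data$se),
      truth = .data$truth[1],
      .groups = "drop") |>
    dplyr::mutate(
      mc_se_coverage = 100 * sqrt(.data$coverage_pct / 100 *
                                    (1 - .data$coverage_pct / 100) /
                                    .data$n_converged),
      link = scn$link, n_subjects = scn$n_subjects,
      total_effect = scn$total_effect, distribution = scn$distribution,
      n_reps = scn$n_reps, seed = scn$seed) |>
    dplyr::arrange(match(.data$method, all_methods))
  frac_bad <- 1 - max(out$n_converged) / scn$n_reps
  if (frac_bad > 0.10) {
    warn(sprintf("%.0f%% of replicates dropped for non-convergence.", 100 * frac_bad))
    out$high_nonconvergence <- TRUE
  }
  if (keep_estimates) attr(out, "estimates") <- est
  class(out) <- c("medtotal_result", class(out))
  out
}

#' Run a list of scenarios
#'
#' @param scenarios List of [scenario()] objects.
#' @param parallelism Worker processes, applied across replicates within each
#'   scenario; results do not depend on it.
#' @inheritParams run_scenario
#' @return A tibble binding the [run_scenario()] results in input order; a
#'   scenario that errors contributes zero rows and a warning, without
#'   stopping the others.
#' @export
run_grid <- function(scenarios, parallelism = 1, methods = all_methods,
                     nodes = 7) {
  if (!length(scenarios)) abort("`scenarios` must be a non-empty list.")
  res <- lapply(seq_along(scenarios), function(i) {
    tryCatch(run_scenario(scenarios[[i]], methods = methods, nodes = nodes,
                          parallelism = parallelism),
             error = function(e) {
               warn(sprintf("scenario %d failed: %s", i, conditionMessage(e)))
               NULL
             })
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("medtotal_result", class(out))
  out
}

#' Lay out results as a report table
#'
#' Reshapes a stack of scenario results into the familiar wide layout: one
#' row per level of the varied factor, and Bias/Coverage/Power columns per
#' method. Bias is rounded to 1 decimal, coverage and power to integers.
#' The unscaled estimator is only shown for the sample-size layout; on its
#' own scale it is not comparable with the others.
#'
#' @param results A tibble from [run_scenario()]/[run_grid()].
#' @param style Which factor varies: `"sample_size"`, `"effect_size"` or
#'   `"effect_distribution"`.
#' @return A wide tibble.
#' @export
render_table <- function(results, style = c("sample_size", "effect_size",
                                            "effect_distribution")) {
  style <- match.arg(style)
  key <- switch(style, sample_size = "n_subjects",
                effect_size = "total_effect",
                effect_distribution = "distribution")
  fixed <- setdiff(c("n_subjects", "total_effect", "distribution"), key)
  for (f in fixed) {
    if (length(unique(results[[f]])) > 1) {
      abort(sprintf("`%s` varies across results; it must be fixed for style '%s'.",
                    f, style))
    }
  }
  methods <- intersect(all_methods, unique(results$method))
  if (style != "sample_size") methods <- setdiff(methods, "nlmm_unscaled")
  results |>
    dplyr::filter(.data$method %in% methods) |>
    dplyr::transmute(.data$link, !!rlang::sym(key), method = .data$method,
                     bias = round(.data$bias_pct, 1),
                     coverage = round(.data$coverage_pct),
                     power = round(.data$power_pct)) |>
    tidyr::pivot_wider(names_from = "method",
                       values_from = c("bias", "coverage", "power"),
                       names_glue = "{method}_{.value}") |>
    dplyr::arrange(.data$link, !!rlang::sym(key))
}

#' Aligned-text rendering of a report table
#'
#' @param results,style As in [render_table()].
#' @return The formatted lines, invisibly; printed as a side effect.
#' @export
format_table_text <- function(results, style = "sample_size") {
  tab <- render_table(results, style)
  txt <- utils::capture.output(print(as.data.frame(tab), row.names = FALSE))
  cat(txt, sep = "\n")
  invisible(txt)
}

#' Power curves across a grid of scenarios
#'
#' @param results A [run_grid()] result where `n_subjects` or `total_effect`
#'   varies.
#' @param x Which column to place on the x axis (default `"n_subjects"`).
#' @return A ggplot.
#' @export
plot_power_curve <- function(results, x = "n_subjects") {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data[[x]], y = .data$power_pct,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$link)) +
    ggplot2::labs(x = x, y = "Power (%)", colour = "Estimator") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.medtotal_result <- function(object, ...) plot_power_curve(object, ...)
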