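small_scn <- function(link = "logit", seed = 301, n_reps = 4, n = 60,
                      total = 0.6) {
  scenario(link, n, total, "equal", n_reps = n_reps, seed = seed)
}

test_that("replicate seeding makes runs deterministic and parallelism-invariant", {
  s <- small_scn()
  r1 <- run_scenario(s, methods = "nlmm_scaled_true", nodes = 7)
  r2 <- run_scenario(s, methods = "nlmm_scaled_true", nodes = 7)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  r4 <- run_scenario(s, methods = "nlmm_scaled_true", nodes = 7, parallelism = 2)
  expect_equal(as.data.frame(r1), as.data.frame(r4))
})

test_that("scenario results are well-formed with binomial Monte-Carlo errors", {
  s <- small_scn("probit", seed = 55, n_reps = 8, n = 100, total = 0.6)
  # tiny cohorts occasionally land on degenerate fits; the >10% exclusion
  # warning is expected behaviour at 8 replicates, not a failure
  r <- suppressWarnings(run_scenario(s, nodes = 7, keep_estimates = TRUE))
  expect_setequal(r$method, c("nlmm_unscaled", "nlmm_scaled_true",
                              "nlmm_scaled_estimated", "sem_ml"))
  expect_true(all(r$coverage_pct >= 0 & r$coverage_pct <= 100))
  expect_true(all(r$power_pct >= 0 & r$power_pct <= 100))
  expect_true(all(r$n_converged <= s$n_reps))
  pv <- r$coverage_pct / 100
  expect_equal(r$mc_se_coverage, 100 * sqrt(pv * (1 - pv) / r$n_converged))
  est <- attr(r, "estimates")
  expect_equal(sort(unique(est$replicate)), 1:8)
  # truths: conditional for rescaled methods, attenuated for the raw one
  expect_equal(unique(est$truth[est$method == "nlmm_scaled_true"]), 0.6)
  expect_equal(unique(est$truth[est$method == "nlmm_unscaled"]),
               as.numeric(unscaled_truth("probit", s$params)))
})

test_that("flipping the sign of the total effect flips estimates symmetrically", {
  sp <- small_scn("probit", seed = 77, n_reps = 6, n = 80, total = 0.6)
  sm <- small_scn("probit", seed = 77, n_reps = 6, n = 80, total = -0.6)
  rp <- run_scenario(sp, methods = "nlmm_scaled_true", nodes = 7,
                     keep_estimates = TRUE)
  rm <- run_scenario(sm, methods = "nlmm_scaled_true", nodes = 7,
                     keep_estimates = TRUE)
  # same relative bias convention regardless of sign, and comparable power
  expect_equal(sign(rp$truth), -sign(rm$truth))
  expect_true(abs(rp$power_pct - rm$power_pct) <= 40)
  expect_true(all(attr(rm, "estimates")$estimate < 0) ||
                mean(attr(rm, "estimates")$estimate) < 0)
})

test_that("run_grid preserves order and survives a failing scenario", {
  s1 <- small_scn("logit", seed = 91, n_reps = 3)
  s2 <- small_scn("probit", seed = 92, n_reps = 3)
  g <- run_grid(list(s1, s2), methods = "nlmm_scaled_true", nodes = 7)
  expect_equal(unique(g$link), c("logit", "probit"))
  expect_error(run_grid(list()), "non-empty")

  # a scenario whose outcome is always 1 (huge latent mean): every fit errors
  s_bad <- scenario("logit", 60, 0.6, "equal", n_reps = 3, seed = 91,
                    nuisance = nuisance_config(alpha1 = 60))
  expect_warning(g2 <- run_grid(list(s_bad, s2), methods = "nlmm_scaled_true",
                                nodes = 7),
                 "failed")
  expect_equal(unique(g2$link), "probit")
})

test_that("report tables pivot to the published layout", {
  s1 <- small_scn("logit", seed = 91, n_reps = 3)
  r <- run_scenario(s1, nodes = 7)
  tab <- render_table(r, "sample_size")
  expect_equal(nrow(tab), 1)
  expect_true(all(c("nlmm_unscaled_bias", "nlmm_scaled_true_coverage",
                    "sem_ml_power") %in% names(tab)))
  # unscaled column dropped outside the sample-size layout
  tab2 <- render_table(r, "effect_size")
  expect_false(any(grepl("unscaled", names(tab2))))
  # coverage/power are integers, bias has one decimal
  expect_true(all(tab$nlmm_scaled_true_coverage ==
                    round(tab$nlmm_scaled_true_coverage)))
  expect_output(format_table_text(r, "sample_size"), "nlmm_scaled_true")
  # mixed nuisance dimensions are rejected
  r_mix <- dplyr::bind_rows(r, dplyr::mutate(r, total_effect = 0.9))
  expect_error(render_table(r_mix, "sample_size"), "varies")
})

test_that("power plots build without evaluation errors", {
  s1 <- small_scn("logit", seed = 91, n_reps = 3)
  r <- run_scenario(s1, nodes = 7)
  pl <- plot_power_curve(r)
  expect_s3_class(pl, "ggplot")
  expect_s3_class(autoplot(r), "ggplot")
})
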