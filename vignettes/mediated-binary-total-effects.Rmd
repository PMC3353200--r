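---
title: "Total effects of a repeated binary predictor on a repeated binary outcome with a continuous mediator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total effects of a repeated binary predictor on a repeated binary outcome with a continuous mediator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtotal)
```

## The problem

Consider a prospective cohort in which a binary exposure $z_{ij}$ (say,
heavy alcohol use), a continuous mediator $M_{ij}$ (antiretroviral
adherence) and a binary outcome $Y_{ij}$ (low CD4 count) are measured at
$j = 1, \dots, 6$ equally spaced visits, with a continuous baseline
covariate $w_i$ (age). The exposure may act on the outcome directly and
through the mediator. When the scientific question is the *total* effect of
the exposure — direct plus indirect — a binary-outcome mixed model that
simply omits the mediator is a natural analysis. This package implements
that analysis and the machinery needed to interpret it correctly, together
with a simulation harness that quantifies its operating characteristics.

## The generative model

Data are generated from a latent-growth structural model. Dropping the
subject index, the latent outcome at visit $j$ is

$$Y^*_j = U_1 + t_j U_2 + \lambda M_j + \kappa z_j + \varepsilon_j,
\qquad Y_j = \mathbb{1}(Y^*_j > 0),$$

with a latent intercept and slope

$$U_1 = \alpha_1 + \gamma_2 w + \zeta_1, \qquad U_2 = \alpha_2 + \zeta_2,
\qquad \mathrm{cov}(\zeta_1, \zeta_2) = \Psi,$$

and a mediator driven by the exposure,

$$M_j = \alpha_3 + \gamma_1 z_j + \zeta_{2+j}, \qquad
\zeta_{2+j} \sim N(0, \theta).$$

The measurement error $\varepsilon_j$ is standard normal (probit link) or
standard logistic with variance $\pi^2/3$ (logit link). The total effect of
$z$ on the latent outcome, conditional on the random effects and the
mediator residual, is $\kappa + \lambda\gamma_1$: $\kappa$ is the direct
path and $\lambda\gamma_1$ the indirect path through the mediator.

`make_scenario()` builds a parameter set from a target total effect and a
direct/indirect split; `generate_dataset()` draws a cohort. Logistic errors
are produced by the inverse-CDF transform of a uniform draw so that a seed
pins down the dataset exactly on every platform.

## Estimators

Four total-effect estimators are provided.

**Mediator-excluded NLMM, unscaled** (`fit_nlmm()` +
`unscaled_total_effect()`). The mixed model
$Y^*_j = \beta_0 + \beta_1 w + \beta_2 t_j + \beta_3 z_j + b_1 + b_2 t_j + e_j$
omits $M$, so $\beta_3$ is a total effect — but on a scale that is marginal
over the mediator residual. Under the probit link, marginalising the normal
term $\lambda\zeta_{2+j}$ into the unit-variance error divides every
coefficient by $\sqrt{1 + \lambda^2\theta}$ exactly; $\beta_3$ targets
$(\kappa + \lambda\gamma_1)/\sqrt{1 + \lambda^2\theta}$. Under the logit
link the analogous factor is
$\sqrt{(\pi^2/3 + \lambda^2\theta)/(\pi^2/3)}$, but only approximately: a
normal plus a logistic variate is not logistic. `unscaled_truth()` returns
this attenuated target and flags the logit case as approximate.

**Scaled NLMM** (`rescale_total_effect()`). Multiplying $\hat\beta_3$ and
its SE by the scale factor restores the mediator-conditional scale. With
known $(\lambda, \theta)$ this is the `nlmm_scaled_true` method; in
practice the factor is estimated — $\hat\lambda$ as the mediator
coefficient of the mediator-*included* mixed model, $\hat\theta$ as the ML
residual variance of the mediator regression `fit_mediator_lm()` — and
their uncertainty enters the SE by the delta method
(`nlmm_scaled_estimated`). The correlation between $\hat\beta_3$ and
$(\hat\lambda, \hat\theta)$, which come from different fits on the same
data, is ignored; this is an approximation, and the estimator-agreement
test bounds its practical consequence.

**Two-equation ML / product of coefficients**
(`product_of_coefficients()`, method `sem_ml`). The structural model's
likelihood factorises into the mediator regression times the
mediator-conditional outcome model, so fitting those two pieces by ML and
combining $\hat\beta_3 + \hat\alpha_1\hat\beta_4$ is the ML estimate of the
total effect under the generative model. Its delta-method variance uses the
within-fit covariance of $(\hat\beta_3, \hat\beta_4)$ and treats the two
fits as independent.

Every estimate carries an explicit `scale` label
(`conditional_on_mediator` vs `marginal_of_mediator`); quantities on
different scales are never compared by the reporting code.

## Maximum-likelihood fitting

The marginal likelihood integrates the Bernoulli likelihood over the
correlated random intercept and slope. With a random slope over six visits,
naive Gauss–Hermite quadrature is inaccurate, so the integral is computed
adaptively: per subject, a damped Newton search finds the posterior mode of
$(b_1, b_2)$, the quadrature grid is re-centred there and re-scaled by the
curvature, and a tensor product of Gauss–Hermite nodes evaluates the
integral. The score and observed information are computed in the same pass
from the posterior-expectation identities
$\partial \log L = E[\partial h]$ and
$\partial^2 \log L = E[\partial^2 h] + \mathrm{Var}[\partial h]$, with the
covariance parameterised through the log-Cholesky factor of $\Psi$ so the
fit is unconstrained apart from a floor of $10^{-3}$ on the Cholesky
diagonal (a random-effect standard deviation of essentially zero).

Fitting is full Newton with a line search, starting from an ordinary GLM
fit, with a quasi-Newton fallback. Convergence is declared when the largest
score component is below $10^{-5}$, or when the Newton decrement — the
achievable log-likelihood gain along identifiable directions — falls below
$10^{-8}$. The second clause matters in replicates where the slope variance
or the intercept–slope correlation sits on the boundary of the parameter
space ($\hat\rho = \pm 1$): there a component of the raw score need not
vanish even though the fixed effects are fully determined, and insisting on
a vanishing score would discard legitimate fits. Standard errors are Wald,
from the inverse observed information, and all tests and intervals are
two-sided Wald at 5%.

Quadrature accuracy: 15 nodes per dimension is the `fit_nlmm()` default;
the likelihood changes by less than $10^{-4}$ between 15 and 40 nodes on
generated cohorts, and by about $10^{-6}$ against brute-force grid
integration on small instances. The simulation harness uses 7 nodes per
dimension, where the adaptive rule is already accurate to well under the
Monte-Carlo noise of any summary it feeds; five nodes is noticeably less
smooth as a function of the parameters and is not used.

## The simulation harness

`scenario()` + `run_scenario()` reproduce the evaluation design: replicate
cohorts are generated with per-replicate seeds derived deterministically
from the scenario seed by a counter scheme, so serial and parallel runs
give identical results. Per replicate the harness fits the
mediator-excluded model, the mediator regression and the mediator-included
model, forms the four estimates, and summarises percent bias
($100(\bar{\hat\tau} - \tau)/\tau$, negative when effects are
underestimated), coverage of nominal 95% intervals, and power of the Wald
test at 5%. The truth is $\kappa + \lambda\gamma_1$ for
conditional-scale methods and the attenuated `unscaled_truth()` for the
raw estimator. Replicates whose fit did not converge are dropped from all
metrics and counted; a scenario with more than 10% exclusions is flagged.
`render_table()` lays results out in the familiar wide format (the
unscaled column appears only in the sample-size layout — on its own scale
it is not comparable with the rest).

## Default study conditions

The literature this design follows prints the structural effect sizes but
not the nuisance parameters, so the package fixes a documented set of
defaults and treats them as *the* study conditions:

| quantity | default | rationale |
|---|---|---|
| $\alpha_1, \alpha_2, \alpha_3$ | 0 | centre the latent scale; prevalence near 1/2 |
| $\gamma_2$ | 0.2 | a modest baseline-covariate effect |
| $w$ | $N(0, 1)$ | standardised baseline covariate |
| $z_{ij}$ | Bernoulli(0.5), independent over visits | maximal information; no serial structure |
| $t_j$ | $0, 1, \dots, 5$ | six equally spaced visits |
| $\Psi$ | diag(0.5, 0.05) | substantial subject heterogeneity, modest slope spread |
| $\lambda$ | 1 | only $\lambda\gamma_1$ is identified by a total effect; the split is a convention |
| $\theta$ | 0.15 (probit), 0.17 (logit) | sets $\lambda^2\theta$ so the unscaled estimator is attenuated by about 7% / 3%, matching the reported behaviour of the mediator-excluded model |

All are overridable through `nuisance_config()`. "Primarily direct" and
"primarily indirect" splits assign 75% of the total effect to the dominant
path (`direct_fraction = 0.75`).

What the generator does *not* emulate: missing or unequally spaced visits,
serially correlated exposure, multiple mediators, and mediator residual
correlation over time. Passing simulations therefore certify the
estimators under the stated conditions, not under every perturbation a
real cohort may exhibit. Because the nuisance values behind the published
tables are unknown, quantities that depend on them strongly — power, and
to a lesser degree bias at small $n$ — are checked for direction and
order, while coverage, which is robust to the nuisance configuration, is
checked against the printed values.

## Worked example

```{r example, eval = FALSE}
params <- make_scenario("probit", total_effect = 0.3, distribution = "equal")
d <- generate_dataset(params, study_design(500), seed = 1)
total_effect_estimates(d, "probit", params = params, nodes = 7)
```

A typical run of the coverage scenarios (300 replicates, n = 500):

```{r coverage, eval = FALSE}
run_scenario(scenario("logit", 500, 0.3, "equal", n_reps = 300, seed = 101),
             methods = c("nlmm_scaled_true", "sem_ml"), nodes = 7)
```

The test suite runs these at 300 replicates; the acceptance script
(`scripts/acceptance.R`) re-runs the full set from scratch at any seed.

## Numerical choices and limitations

* **Problem sizes.** Validation uses cohorts of 500 subjects for coverage
  (300 replicates per scenario), 2,000–5,000 for parameter recovery and
  10,000 for the attenuation identity — sizes at which Monte-Carlo error is
  small against the assertions made.
* **Mediator regression.** Fit with independent errors, matching the
  generator; $\theta$ in the scale factor is the residual variance.
  $\mathrm{Var}(\hat\theta) = 2\hat\theta^2/N$ is used in the delta method.
* **Bias sign convention.** Bias is reported as
  $(\text{observed} - \text{true})/\text{true}$, so underestimation is
  negative.
* **Non-convergence.** Dropped and counted, never retried with fresh data;
  at the default conditions exclusions are rare (well under 1%).
* **Boundary fits.** Replicates with $\hat\Psi$ singular are kept (see the
  convergence rule above); their fixed effects and SEs are well defined.
* **Ties between links.** Logit-vs-probit coefficient ratios are only
  checked as a sanity band (1.4–2.0); there is no exact identity.
* **Out of scope.** Weighted-least-squares structural-equation estimation
  (the approach whose positive bias motivates the ML routes here), missing
  data, and indirect-effect inference by the difference-of-coefficients
  method, which is scale-inconsistent for binary outcomes.
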