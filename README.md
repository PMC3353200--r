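# medtotal

Estimating the **total effect** of a repeated binary predictor on a
repeated binary outcome when a continuous mediator sits on the causal
path — and knowing which scale that estimate lives on.

## The problem

In longitudinal cohorts (the motivating setting is heavy alcohol use,
antiretroviral adherence and HIV disease progression), an exposure $z_{ij}$
may act on a binary outcome $Y_{ij}$ both directly and through a continuous
mediator $M_{ij}$. Writing the outcome through a latent variable
$Y_j^* = U_1 + t_j U_2 + \lambda M_j + \kappa z_j + \varepsilon_j$ with
$Y_j = 1(Y_j^* > 0)$, a latent growth structure
$U_1 = \alpha_1 + \gamma_2 w + \zeta_1$, $U_2 = \alpha_2 + \zeta_2$, and a
mediator model $M_j = \alpha_3 + \gamma_1 z_j + \zeta_{2+j}$,
$\zeta_{2+j} \sim N(0,\theta)$, the total effect is
$\kappa + \lambda\gamma_1$.

A binary-outcome mixed model that simply omits the mediator,

$$Y^*_j = \beta_0 + \beta_1 w + \beta_2 t_j + \beta_3 z_j + b_1 + b_2 t_j + e_j,$$

estimates a total effect in $\beta_3$ — but on a scale marginal to the
mediator residual. Probit/logit coefficients are defined relative to a
fixed residual variance, so $\beta_3$ is attenuated by
$\sqrt{1+\lambda^2\theta}$ (probit; for logit,
$\sqrt{(\pi^2/3+\lambda^2\theta)/(\pi^2/3)}$, approximately). The package
provides:

* a seeded **generator** for mediated longitudinal binary cohorts
  (`make_scenario()`, `generate_dataset()`);
* maximum-likelihood **mixed-model fitting** with correlated random
  intercept and slope by adaptive Gauss–Hermite quadrature, implemented in
  compiled code with analytic score and observed information
  (`fit_nlmm()`, `marginal_loglik()`, `fit_mediator_lm()`);
* **scale conversion** and total-effect construction: true- and
  estimated-factor rescaling with delta-method SEs, and the two-equation
  ML product-of-coefficients route (`scale_factor()`,
  `rescale_total_effect()`, `product_of_coefficients()`,
  `total_effect_estimates()`);
* a **Monte-Carlo harness** for bias, coverage and power across scenario
  grids (`scenario()`, `run_scenario()`, `run_grid()`, `render_table()`,
  `plot_power_curve()`).

Everything is data-frame-in / tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods. A thin CLI
(`inst/cli/medtotal`, subcommands `make-data`, `analyze`, `simulate`)
wraps the same functions.

## Worked example

```r
library(medtotal)

params <- make_scenario("probit", total_effect = 0.3, distribution = "equal")
d <- generate_dataset(params, study_design(500), seed = 1)
total_effect_estimates(d, "probit", params = params, nodes = 7)
#> # A tibble: 4 × 9
#>   method                scale                   estimate     se ci_low ci_high   p_value approximate converged
#>   <chr>                 <chr>                      <dbl>  <dbl>  <dbl>   <dbl>     <dbl> <lgl>       <lgl>
#> 1 nlmm_unscaled         marginal_of_mediator       0.241 0.0558  0.131   0.350 0.0000165 FALSE       TRUE
#> 2 nlmm_scaled_true      conditional_on_mediator    0.258 0.0599  0.141   0.375 0.0000165 FALSE       TRUE
#> 3 nlmm_scaled_estimated conditional_on_mediator    0.256 0.0596  0.140   0.373 0.0000168 FALSE       TRUE
#> 4 sem_ml                conditional_on_mediator    0.260 0.0596  0.143   0.377 0.0000127 FALSE       TRUE
```

Row 1 is the raw mediator-excluded coefficient: a total effect, but
attenuated (its population target here is
$0.3/\sqrt{1.15} \approx 0.280$, not $0.3$). Rows 2–3 rescale it to the
mediator-conditional scale using the true and the estimated scale factor;
row 4 reaches the same scale by summing the direct path and the product of
the mediator paths from a two-equation ML fit. On this cohort all three
conditional-scale estimates sit within one standard error of the true
total effect 0.3, and the `scale` column makes explicit which numbers may
be compared.

A small simulation:

```r
r <- run_scenario(scenario("logit", 500, 0.3, "equal", n_reps = 300, seed = 101),
                  methods = c("nlmm_scaled_true", "sem_ml"), nodes = 7)
r[, c("method", "bias_pct", "coverage_pct", "power_pct", "n_converged")]
#> # A tibble: 2 × 5
#>   method           bias_pct coverage_pct power_pct n_converged
#>   <chr>               <dbl>        <dbl>     <dbl>       <int>
#> 1 nlmm_scaled_true    0.816           93        93         300
#> 2 sem_ml              1.94            93        93         300
```

Both conditional-scale estimators are nearly unbiased for the total
effect, with coverage within Monte-Carlo error of the nominal 95% — the
scaled mixed model achieves this without ever modelling the mediation
paths in the outcome model.

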