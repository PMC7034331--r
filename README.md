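# voisynth

Value-of-information (VoI) analysis for Bayesian multiparameter evidence
synthesis: which parameter uncertainties drive the uncertainty in a model's
estimates, what a future study of a given design and size would be expected
to contribute, and how large that study should be once sampling costs are
counted.

The package is aimed at analysts running evidence-synthesis or other
MCMC-fitted graphical models who want decision-theoretic sensitivity analysis
and research prioritization on top of an existing posterior sample. It
implements:

* **EVPI / EVPPI / EVSI** for decision problems whose optimal expected loss
  is a function `h(E(alpha))` of the mean outputs: finite action sets, scalar
  point estimation under squared-error loss (where EVPPI is the expected
  variance reduction, `var(alpha) - E_phi[var(alpha | phi)]`), and vector
  estimation under A-optimal (`c' cov(alpha) c`) and D-optimal
  (`det cov(alpha)`) losses.
* The **single-loop regression estimator**: write
  `alpha = g(phi) + e`, fit `g` by nonparametric regression (penalized
  splines via mgcv by default, an in-package MARS as an alternative) across
  posterior draws, and estimate the conditional-loss term from fitted values
  and residuals — no nested simulation, no model refits. EVSI uses the same
  machinery with a sufficient statistic of a simulated future dataset as the
  predictor. Standard errors come from simulating the regression
  coefficients.
* **Expected net benefit of sampling**: monetize an EVSI curve (willingness
  to pay per unit, or per halving, of variance), subtract per-participant
  costs, and locate the optimal sample size on a smoothed monotone curve.
* A complete **evidence-synthesis model of HIV prevalence among MSM in
  London (2012)** as the worked example: three subgroups (GUM-clinic
  attenders, non-attenders, former MSM), six surveillance/survey data
  sources, fitted with JAGS, with two structural variants and posterior
  predictive simulators for two candidate future studies.
* **Conjugate oracles** (closed forms, exact enumeration, nested Monte
  Carlo) that verify every estimator in the test suite.

## Worked example

Fit the base-case HIV model, ask which parameter drives the uncertainty in
the undiagnosed NGMSM case count, and value a future anonymous clinic survey:

```r
library(voisynth)

fit <- sample_posterior(hiv_observations(), hiv_variant(), seed = 1)
posterior_summaries(fit, c("mu_U_2grp", "mu_UN", "pidelta_G"))
#> # A tibble: 3 x 6
#>   quantity    median     mean      sd    lower    upper
#>   <chr>        <dbl>    <dbl>   <dbl>    <dbl>    <dbl>
#> 1 mu_U_2grp 797.     844.     315.    373.     1607.
#> 2 mu_UN     669.     719.     298.    291.     1447.
#> 3 pidelta_G   0.0563   0.0925   0.101   0.0218    0.405
```

About 800 MSM in London are estimated to live with undiagnosed HIV
(95% credible interval roughly 370–1600), most of them clinic non-attenders.
How much of the variance of `mu_UN` would vanish if we knew the prevalence
`pi_GA` that the GUM Anon survey measures?

```r
evppi(fit, "pi_GA", loss_quadratic("mu_UN"), seed = 1)
#> <voi_estimate> EVPPI under scalar_quadratic loss on (mu_UN) given (pi_GA)
#>   value = 14819.3 (SE 12.1), baseline loss = 88680.5, residual loss = 73861.2, proportion = 0.167
```

Under the strong cascade priors, GUM Anon could remove only ~17% of that
variance. Drop those priors (`hiv_variant("gum_anon_only")`) and the picture
sharpens — the survey then carries over half of the information about
`mu_UN` — which is what makes a top-up survey worth costing out:

```r
va <- sample_posterior(variant = hiv_variant("gum_anon_only"), seed = 2)
curve <- evsi_curve(va, "gum_anon", c(1, seq(25, 400, by = 25)),
                    loss_quadratic("mu_U_2grp"), seed = 2)
lambda <- 5000 / (3271^2 - 2771^2)   # pay 5000 to cut the SD by 500
enbs <- enbs_curve(curve, benefit_spec("linear_variance", lambda), cost_spec(17))
attr(enbs, "n_star")
#> [1] 154
autoplot(enbs)
```

At 17 currency units per participant, sampling about 150 further
participants maximizes the expected net benefit. Every estimate above is a
Monte Carlo quantity; seed-to-seed variation at these fit sizes is a few
percent (and tens of participants for `n_star`).

## Package tour

| Area | Functions |
| --- | --- |
| Draws and losses | `read_draws()`, `check_draws()`, `loss_quadratic()`, `loss_finite_action()`, `loss_a_optimal()`, `loss_d_optimal()` |
| Estimators | `evpi()`, `evppi()`, `evsi()`, `evppi_grid()`, `voi_standard_error()`, `fit_conditional_mean()` |
| HIV model | `hiv_observations()`, `hiv_variant()`, `sample_posterior()`, `derived_outputs()`, `log_posterior()`, `posterior_summaries()` |
| Future studies & ENBS | `simulate_gum_anon()`, `simulate_gmshs()`, `evsi_curve()`, `benefit_spec()`, `cost_spec()`, `enbs_curve()` |
| Oracles | `conjugate_fixture()`, `generate_draws()`, `closed_form_evppi()`, `exact_evsi_enumeration()`, `nested_mc_evppi()` |
| Plots / tidiers | `plot_evppi_grid()`, `plot_evsi_curve()`, `autoplot()`, `tidy()`, `glance()`, `glance_mcmc()` |

A command-line wrapper (`exec/voisynth`) exposes `fit`, `evppi-grid`,
`evsi`, `enbs`, and `test-oracles` subcommands over YAML configs. The
methods vignette (`vignettes/value-of-information.Rmd`) documents the model,
its assumptions, and every numerical design choice.
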