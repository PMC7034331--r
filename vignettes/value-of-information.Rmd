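---
title: "Value of information for Bayesian evidence synthesis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value of information for Bayesian evidence synthesis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multiparameter evidence synthesis (MPES) estimates quantities that no single
dataset measures, by linking several indirect data sources through a directed
acyclic graph of model assumptions and fitting the joint posterior by MCMC.
Once such a model is in routine use, two questions follow naturally:

* **Sensitivity**: which parameter uncertainties drive the uncertainty in each
  estimate?
* **Design**: which future dataset, and how large, would most improve the
  estimates — and is it worth its cost?

Both are questions about the *expected value of information*. Writing
$\alpha$ for the decision-relevant model outputs, the expected value of
partial perfect information for a parameter subset $\phi$ is

$$\mathrm{EVPPI}(\phi) = E_\theta\,L(d^*,\theta) -
  E_\phi\!\left[E_{\theta\mid\phi}\,L(d^*_\phi,\theta)\right],$$

the expected reduction in the loss of the optimal decision if $\phi$ were
learnt exactly, and the expected value of sample information
$\mathrm{EVSI}(y)$ replaces "learning $\phi$" with "observing a future
dataset $y$ of a concrete design". `voisynth` implements these for any
decision problem in which the optimal expected loss is a known function
$h(E(\alpha))$ of the mean of the outputs, which covers:

* **finite action sets** — one loss column per action, $h = \min_d$;
* **scalar point estimation** under squared error — the loss is the posterior
  variance, so EVPPI/EVSI are expected variance reductions;
* **vector point estimation** with A-optimal ($c'\,\mathrm{cov}(\alpha)\,c$)
  or D-optimal ($\det \mathrm{cov}(\alpha)$, optionally $\det^{1/S}$) losses.
  A-optimality values equal *absolute* variance reductions equally;
  D-optimality values equal *relative* reductions equally, which matters when
  the components of $\alpha$ live on different scales (a prevalence and a
  case count, say).

# The single-loop regression estimator

Nested Monte Carlo evaluation of the double expectation is prohibitively
expensive at posterior scale. Instead, every estimator in this package uses
the single-loop regression idea: write

$$\alpha = E(\alpha \mid \phi) + \varepsilon = g(\phi) + \varepsilon,$$

fit $g$ by nonparametric regression across the posterior draws
$(\alpha^{(k)}, \phi^{(k)})$, and plug the fitted values into $h$. For
quadratic loss the conditional variance is estimated by the mean squared
residual, so

$$\widehat{\mathrm{EVPPI}} = \widehat{\mathrm{var}}(\alpha) -
  \tfrac{1}{K-1}\textstyle\sum_k \big(\alpha^{(k)} - \hat g(\phi^{(k)})\big)^2,$$

equivalently (exactly so for an unpenalized fit) the variance of the fitted
values. For vector losses, componentwise regressions give a covariance matrix
of residuals, and the estimate is $v(\mathrm{cov}(\alpha)) -
v(\mathrm{cov}(\text{residuals}))$. For EVSI the conditioning variable is a
low-dimensional *sufficient statistic* $T(y)$ of a future dataset, one
simulated from the posterior predictive per draw, so no refitting of the
model is ever needed.

**Standard errors** come from simulating regression coefficient vectors from
their (Bayesian posterior or asymptotic) normal distribution, recomputing the
VoI from each perturbed set of fitted values, and taking the standard
deviation (default 200 simulations, seeded). Two properties are worth
knowing. First, this captures regression-coefficient uncertainty, not the
Monte Carlo variation of the draws themselves; the test suite therefore
verifies estimator accuracy against oracles with *replication-based* standard
errors. Second, for quadratic loss the residual-loss perturbation is
second-order (residuals are orthogonal to the fitted space), so these SEs
shrink roughly like $1/K$ rather than $1/\sqrt K$; for finite-action losses
the usual $1/\sqrt K$ law holds.

**Regression backends.** The default is a penalized regression spline via
`mgcv::gam` (REML), with a thin-plate smooth for one parameter, a tensor
product for two or three, and additive smooths for four or five; beyond five
the functions refuse and advise reducing the conditioning set. A compact
in-package MARS implementation (hinge basis, greedy forward selection,
backward pruning by GCV with penalty 3 per knot, interaction degree 2,
up to 21 basis functions) is available as `method = "mars"`; being an
unpenalized least-squares fit on the selected basis it satisfies the
variance-decomposition identity exactly and its coefficient uncertainty is
the classical `lm` covariance (conditional on basis selection). Degenerate
(constant) predictors are dropped; responses with fewer than four distinct
predictor values fall back to linear terms, which makes small-count
statistics (a binary future observation, say) exact group means.

# The worked example: HIV prevalence in London MSM

The flagship application estimates, for men who have sex with men (MSM) in
London in 2012, the prevalence of diagnosed and undiagnosed HIV and the
corresponding case counts, in three subgroups: attenders of genitourinary
medicine (GUM) clinics in the past year (GMSM), non-attenders (NGMSM), and
former MSM (PMSM). Six data sources inform the graph: a population count, the
NATSAL survey (subgroup shares), the SOPHID and HANDD registers (diagnosed
counts), the GUMCAD clinic testing cascade, the GUM Anon anonymous survey,
and the GMSHS venue survey. Undiagnosed GMSM prevalence decomposes as
$\overline{(\pi\delta)}_G = \pi_{UN} + \pi_{OP}$ (infections missed because a
test was not offered, or was refused), each component built from the cascade
probabilities $\gamma_{1..4}$ and substantive priors; NGMSM undiagnosed
prevalence follows by an odds-ratio link estimated from GMSHS. Diagnosed
fractions use the constraint $\delta_g < 1 - \overline{(\pi\delta)}_g$ via
$\delta_g = a_{\delta g}(1-\overline{(\pi\delta)}_g)$, $a_{\delta g}\sim U(0,1)$.

Two structural variants are toggles on `hiv_variant()`: `"gum_anon_only"`
replaces the cascade-based construction of undiagnosed GMSM prevalence by a
flat $U(0,1)$ prior (so only GUM Anon informs it), and
`gumcad_informs_diagnosed` sets diagnosed GMSM prevalence directly from the
cascade as $(1-\gamma_1) + \gamma_1\gamma_2\gamma_3\gamma_4$.

Design choices a maintainer should know:

* **Population denominator.** The published male population count is cited
  by the sources but not reproduced in them. The package default
  (`ypop = 2,060,000`) is the approximate ONS mid-2012 count of London males
  aged 15–44, the age band this surveillance model family describes. The
  choice matters: every case count scales linearly with it, and diagnosed
  prevalences inversely (their numerators are pinned by register counts).
  It ships as an ordinary config datum (`hiv_observations()`, YAML file in
  `inst/extdata/`) so it can be overridden.
* **PMSM submodel.** Only its existence is specified by the sources.
  We mirror the NGMSM structure with
  $\overline{(\pi\delta)}_P = u_P\,\overline{(\pi\delta)}_N$,
  $u_P \sim U(0,1)$, encoding "much lower prevalence"; PMSM-sensitive
  outputs carry correspondingly more model risk.
* **Two definitions of the undiagnosed total** coexist in the literature on
  this model: `mu_U_2grp` ($\mu_{UG}+\mu_{UN}$) and `mu_U_3grp` (adding
  $\mu_{UP}$). Both are exposed as columns; EVSI/ENBS examples use the
  two-group sum, the multivariate-loss example the three-group sum.
* **NATSAL remainder.** The survey multinomial needs a fourth (non-MSM)
  category; we use a uniform Dirichlet over the four shares.
* **Sampler.** The posterior is sampled with JAGS (Gibbs/slice) via `rjags`,
  the classical engine for this model family. The joint posterior has strong
  correlations and heavy upper tails in the undiagnosed counts (the
  diagnosed-count constraint $\mu_{DG} \ge y_H$ interacts with the subgroup
  share $\rho_G$), so draws are heavily thinned: defaults keep 4 chains of
  5000 draws at thinning 50 (base case) or 100 (GUM-Anon-only variant), and
  the shipped analyses thin to 100/200. Split-$\hat R$ and effective sample
  sizes are attached to every fit; $\hat R > 1.01$ warns but still returns
  draws. All derived quantities are recomputed in R by `derived_outputs()`
  from the monitored founders, so the R graph — which is tested against a
  second literal transcription of the density to $10^{-8}$ — is the single
  source of truth.
* **Support truncation.** Under the GUM-Anon-only variant the free
  undiagnosed prevalence can push the derived survey prevalence
  $\pi_{GA} = (\overline{(\pi\delta)}_G + \pi_{GD})/\gamma_1$ above 1; the
  JAGS program truncates that region exactly with a penalty observation, and
  `log_posterior()` returns $-\infty$ there. The truncated region carries
  negligible posterior mass.

# Future-study designs

Two designs are implemented, each reduced to a scalar statistic so the EVSI
regression stays one-dimensional:

* **GUM Anon top-up** of size $n$: $y \sim \mathrm{Bin}(n, \pi_{GA})$ per
  draw, statistic $T = y/n$.
* **GMSHS repeat** of size $n$: the number of clinic attenders in the sample
  is $N_G \sim \mathrm{Bin}(n, q)$ with $q$ drawn per posterior draw from
  Beta(493.5, 452.5) — the Jeffreys posterior of the attendance split
  observed in the original survey, since no predictive law for attendance is
  specified by the sources; this is the main replication risk for GMSHS
  results. Positives follow per-arm binomials, and the statistic is the
  odds ratio of the Jeffreys-smoothed proportions $(Y+0.5)/(N+1)$, finite in
  every corner including empty arms.

Per-size seeds are derived from `(seed, n)`, so EVSI curves are reproducible
and their Monte Carlo noise is independent across sizes.

# Net benefit of sampling

`enbs_curve()` converts an EVSI curve to money with either a
willingness-to-pay per unit of variance reduction (`linear_variance`) or per
halving of the variance (`halving`), subtracts `fixed + unit_cost * n`, and
reports the argmax. Because per-size EVSI estimates carry independent noise
that jitters the argmax of a flat-topped curve, the EVSI curve is first
isotonized in $n$ (information value cannot decrease with sample size), then
interpolated onto the integer grid with a monotone Hermite spline, so the
optimum is not quantized to the evaluation grid; the raw grid argmax is also
reported. Ties take the first index. Small negative EVSI values are clipped
to zero for the benefit (flagged), never silently in the EVSI tables
themselves, where negative estimates are reported as computed.

# Verification strategy

The oracles module is the backbone: four conjugate fixtures
(`normal_known_var`, `beta_binomial`, `linear_sum`, `two_action_gaussian`)
with closed-form EVPPI, exact EVSI by enumeration or conjugacy, and a nested
Monte Carlo estimator used only as a test oracle. Fixture hyperparameters are
chosen so EVPPI proportions span roughly 10–90% of output variance. The test
suite checks the regression estimators against these oracles with
replication-based standard errors, the orderings
$0 \le \mathrm{EVPPI} \le \mathrm{EVPI}$ and
$\mathrm{EVSI}(n) \uparrow \mathrm{EVPPI}$, per-draw graph identities, prior
recovery by Kolmogorov–Smirnov tests, and the double-implementation density
agreement. What these fixtures do *not* emulate is real surveillance data:
they are exact conjugate worlds with known answers, so passing them shows
the estimators are correct, not that the HIV model is right for London.

Problem sizes were chosen once for desk-scale reproduction: fits of
4 × 5000 retained draws (2500 for the diagnosed-prevalence variant, whose
target is cascade-pinned and tight), EVSI curves on a 17-point grid to 400,
and 20,000-draw fixture checks. The headline surveillance quantities are
Monte Carlo quantities estimated from heavy-tailed posteriors; their
replication spread at these sizes is a few percent, and the acceptance
tolerances (10%, or 15% for count-scale quantities sensitive to the
population-denominator and attendance-predictive choices) reflect that.

# Known limitations

* Gaussian-process and INLA regression backends are out of scope; beyond
  five conditioning parameters the regression refuses rather than degrading
  silently. EVSI requires a low-dimensional sufficient statistic.
* Slice sampling mixes slowly in the heavy upper tail of the diagnosed-GMSM
  prevalence; posterior summaries of that corner (e.g. the base-case
  diagnosed prevalence) need the heavy default thinning, and their means are
  less stable than their medians.
* The population denominator and the PMSM structure are reconstructions of
  unpublished details; count-scale results inherit that uncertainty
  multiplicatively.
* Costs are linear in sample size; portfolio choices between designs are
  reported side by side, not jointly optimized.
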