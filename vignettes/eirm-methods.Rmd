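---
title: "Explanatory item response modeling of DSM-5 SUD criteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explanatory item response modeling of DSM-5 SUD criteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sudirt)
```

## The measurement model

The package analyzes the 11 dichotomous DSM-5 substance use disorder
criteria with the Rasch model. Person $j$ endorses criterion $i$ with
probability

$$P(Y_{ij} = 1) = \frac{\exp(\theta_j - \beta_i)}{1 + \exp(\theta_j - \beta_i)},$$

where $\theta_j$ is the person's position on the disorder continuum and
$\beta_i$ is the criterion *severity*: the latent level at which the
endorsement probability is exactly 0.5. In the equivalent generalized
linear mixed model (GLMM) formulation the item enters as an *easiness*
parameter $\epsilon_i = -\beta_i$ on the logit scale,
$\eta_{ij} = \theta_j + \epsilon_i$, with
$\theta_j \sim N(0, \sigma^2)$ a random person intercept. We report
severity (`fit$severity`) as minus easiness so that higher values mean a
criterion requires a higher disorder level to endorse.

Estimation is marginal maximum likelihood (MML): the person effect is
integrated out of each person's likelihood contribution,

$$\ell = \sum_j \log \int \prod_{i \in \mathrm{obs}(j)}
  p_{ij}(\theta)^{y_{ij}} \bigl(1 - p_{ij}(\theta)\bigr)^{1 - y_{ij}}
  \, \phi(\theta; 0, \sigma^2)\, d\theta ,$$

and the integral is evaluated by Gauss–Hermite quadrature rescaled to
the standard-normal weight. Missing responses simply drop out of the
product; missing *covariates* instead remove the person
(`filter_complete_cases()`), mirroring standard complete-case practice
for the structural part of the model.

## Explanatory extensions

`model_spec()` realizes a small term algebra on top of the item
indicators:

* **person covariates** $Z_{pj}$ with effects $J_p$ (latent regression:
  $\eta_{ij} = \theta_j + \epsilon_i + \sum_p J_p Z_{pj}$, where
  $\theta_j$ is now the *residual* person effect after the covariates);
* **person-by-person interactions** such as gender × alcohol use;
* **item-by-covariate interactions** $W_{ijh}$ with effects $\delta_h$
  — a significant $\delta$ is uniform differential item functioning
  (DIF): the item's severity differs between groups at equal latent
  level;
* **item properties** (LLTM-style), supported by the algebra for
  completeness but not used in the shipped ladder.

The shipped ladder (`canonical_specs()`) is the nested sequence null →
m1 (gender, alcohol) → m2 (+ interaction) → m3 (+ four personality
scores) → m4 (m3 + gender×personality) and m5 (m3 +
alcohol×personality). m5 is compared against m3, in which it is nested,
not against m4. Parameter counts are 12, 14, 15, 19, 23 and 23 (11
items + covariate terms + 1 variance).

Model comparison uses likelihood-ratio tests on deviance differences
plus AIC and BIC. **BIC's sample size is the number of observed
response cells** (persons × items minus missing), not the number of
persons: with 573 persons × 11 items = 6303 cells, a deviance of 5648.6
and 19 parameters give AIC 5686.6 and BIC 5814.8 — internally
consistent arithmetic that the package's `aic()`/`bic()` reproduce
exactly. Reports label the −2·log-likelihood row "deviance".

Inference on individual terms is Wald ($z = \hat\gamma/\mathrm{SE}$,
normal reference, no small-sample correction); stars are `***` < .001,
`**` < .01, `*` < .05, with a p exactly at a boundary not starred.

## The DIF scan

`dif_scan()` tests one (item, covariate) interaction at a time, with all
other items anchoring the scale, and refits the base model augmented by
that single term. The one-at-a-time design avoids the exact collinearity
of a full interaction set with the covariate's main effect; whether a
joint model or backward selection would flag the same items is a design
choice we document rather than resolve. Sign convention: a positive
$\hat\delta$ means the item is *easier* to endorse for the indicator-1
group (or for higher covariate values). Benjamini–Hochberg correction
within the scan is available behind `correction = "BH"`; the default is
uncorrected per-test flagging at $\alpha = .05$.

## Numerical choices

* **Quadrature**: 41 non-adaptive Gauss–Hermite nodes by default.
  Adaptivity is deliberately omitted for transparency; the test suite
  shows fitted parameters move by less than $10^{-3}$ between 21 and 61
  nodes at the study's scale, and the 201-node evaluation agrees with a
  20 001-point dense-trapezoid integration to better than $10^{-6}$.
  Non-adaptive rules lose accuracy for person SDs near 2 combined with
  extreme item parameters; for such regimes pass `gh_rule(101)` or
  more.
* **Optimizer**: BFGS on (easiness, effects, $\log\sigma$) with analytic
  gradients. Convergence is declared when the gradient satisfies
  $\max|g| < 10^{-6}(1 + |\ell|)$ — a scale-invariant form of a
  gradient-norm rule, since an absolute cutoff is meaningless when
  $|\ell| \approx 2\times 10^4$. The `converged` flag is honest; ladder
  and scan functions warn or abort on non-convergence rather than
  silently continuing.
* **Standard errors**: observed information by central differences of
  the analytic gradient, step $10^{-4}\max(1, |\hat\gamma|)$.
* **Identification**: no global intercept; 11 item easiness parameters
  plus one variance. An item with all-0 or all-1 responses is refused
  by name (its parameter diverges). Rank-deficient designs raise an
  identifiability error before optimization.
* **EAP scores**: posterior means on the quadrature grid. A person with
  no observed responses receives the prior (EAP 0, posterior SD
  $\hat\sigma$). EAPs are shrunk toward 0; their sample variance is
  strictly below $\hat\sigma^2$, which is why two-step "EAP then
  regress" coefficients are attenuated relative to the joint EIRM
  estimates — the package's tests demonstrate this attenuation
  directly.
* **Score equations**: at an MML optimum the *posterior-weighted*
  expected endorsement equals the observed count per item (equivalently
  the gradient vanishes); the *prior* marginal prevalence
  (`marginal_prevalence()`) matches observed prevalence only
  approximately (≈$10^{-3}$ at n = 400), so tests assert the exact
  identity via the gradient and the marginal approximation at 0.01.

## The synthetic-data generator

No raw clinical data ship with the package, so `simulate_dataset()`
generates datasets with the statistical structure the analysis assumes.
Defaults describe a severe clinical sample of illicit drug users:

* **n = 573 persons**, gender ~ Bernoulli(0.30 female), non-drinking ~
  Bernoulli(0.29), four personality scores multivariate normal
  (identity correlation by default — no inter-factor correlations are
  assumed) then z-standardized;
* **severities** `default_severities()`: all negative (−2.58 to −0.99),
  i.e. every criterion is endorsed by a majority;
* **fixed effects** `default_fixed_effects()`: female −0.42,
  non-drinker −0.76, female×non-drinker +0.92, and per-SD personality
  effects with sensation seeking (0.55) dominant;
* **residual person SD** $\sqrt{2.34} \approx 1.53$ — the residual
  variance after covariate effects. A printed spread of "2.34(1.50)"
  for that model is internally inconsistent ($\sqrt{2.34} = 1.53$),
  while the covariate-free "2.56(1.60)" is exact; we therefore read the
  variance column as authoritative throughout;
* **DIF** `default_dif_map()`: uniform easiness shifts per (item,
  covariate), e.g. −1.23 on Withdrawal for women (harder to endorse at
  equal latent level); injection and scan share the same sign
  convention, so the scan recovers the injected value directly;
* **covariate missingness**: optional person-wise rate (33/606 ≈ 0.054
  reproduces the 606 → 573 complete-case workflow).

The logistic residual of the GLMM formulation (variance $\pi^2/3$) is
not a sampled quantity — it is realized implicitly by Bernoulli
sampling through the logit link, so there is no residual parameter to
set or estimate.

What the generator does *not* emulate: real criterion-level local
dependence beyond the single factor, polytomous or Likert personality
items (factor scores enter directly as covariates), nonuniform DIF
(slope changes — out of scope by design), and multi-drug category
structure. Passing parameter-recovery and calibration tests therefore
demonstrates correctness of the estimator under the stated model, not
robustness to violations of it. Because the covariate scaling of the
original personality scores is unknowable from summaries alone,
z-standardization (per-SD effects) is this package's convention.

## Problem sizes used by the test suite

The suite exercises the estimator at sizes chosen to make Monte Carlo
bands decisive: parameter recovery at n = 5000 (3 seeds; severities
within ±0.12, person SD within ±0.08, fixed effects within ±0.15),
type-I calibration of LR and single-interaction DIF tests at n = 500
over 200 replicates (empirical size within [2%, 9%] at α = .05),
attenuation at n = 2000 over 20 seeds, and DIF recovery of a −1.23
shift at n = 3000 over 20 seeds (±0.35). The replicated simulation
blocks run on a 21-node rule — the quadrature-stability results above
(parameters move < 10⁻³ between 21 and 61 nodes) make the smaller rule
equivalent at these tolerances.

## Known limitations

* Discrimination is fixed at 1 (Rasch); no 2PL extension.
* Nonuniform DIF is not modeled or detected.
* Phi (Pearson) correlations, not tetrachorics, feed the
  unidimensionality descriptives; eigenvalues from binary data are
  therefore deflated relative to a tetrachoric analysis, and both raw
  and reduced (communality-adjusted) eigenvalues are reported because
  the two conventions differ most in the trailing values.
* Non-adaptive quadrature requires more nodes for latent SDs well
  above 2.

## A minimal session

```{r, eval = FALSE}
sim <- simulate_dataset(generation_config(n_persons = 573, seed = 1))
fit <- fit_rasch(sim$responses)
ladder <- run_ladder(sim$responses, sim$covariates)
ladder_table(ladder)
dif <- dif_scan(sim$responses, sim$covariates,
                base_spec = canonical_specs()$m3,
                scan_covariates = "gender_female")
dif_table(dif)
```
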