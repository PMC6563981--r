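# sudirt

Explanatory item response modeling (EIRM) of the 11 dichotomous DSM-5
substance use disorder (SUD) criteria, for psychometricians and
clinical researchers who want measurement and explanation in one
likelihood rather than a two-step "score then regress" analysis.

## The model

Person *j* endorses criterion *i* with Rasch probability

    P(Y_ij = 1) = exp(θ_j − β_i) / (1 + exp(θ_j − β_i)),

with θ_j the latent disorder level and β_i the criterion severity (the
latent level at which endorsement probability is 0.5). Recast as a
logistic GLMM with a random person intercept θ_j ~ N(0, σ²), the model
extends to the explanatory forms:

* latent regression — η_ij = θ_j + ε_i + Σ_p J_p Z_pj, person
  covariates (gender, alcohol use, four personality scores) with fixed
  effects J_p, θ_j now the residual person effect;
* item-by-covariate interactions δ_h W_ijh — uniform differential item
  functioning (DIF) when significant;
* LLTM-style item-property terms.

Estimation is marginal maximum likelihood with Gauss–Hermite
quadrature and analytic gradients; inference is Wald per term and
likelihood-ratio tests plus AIC/BIC across a nested model ladder
(null → gender+alcohol → +interaction → +personality →
gender×personality / alcohol×personality). A one-interaction-at-a-time
DIF scan, EAP scoring, unidimensionality descriptives (eigenvalues,
single-factor loadings, coefficient omega) and a synthetic-data
generator complete the pipeline. See the methods vignette
(`vignettes/eirm-methods.Rmd`) for the assumptions and numerical
choices.

## Worked example

```r
library(sudirt)
sim <- simulate_dataset(generation_config(n_persons = 573, seed = 1))
fit <- fit_rasch(sim$responses)
fit
#> Rasch model (MML, 41 GH nodes)
#>   persons 573, observed cells 6303, loglik -2880.4, deviance 5760.8
#>   person variance 3.27 (SD 1.81)
#>          Larger Cut down Time spent Craving Major role Social Give up Hazard
#> severity  -1.03    -1.78      -1.62   -0.94      -2.05  -2.37    -2.4  -1.23
#>          Consistent use Tolerance Withdrawal
#> severity          -2.51     -1.44      -1.52
```

All severities are negative: in a severe clinical sample every
criterion is endorsed by a majority, so each sits below the average
latent level. Adding the covariates:

```r
f3 <- fit_eirm(sim$responses, sim$covariates, canonical_specs()$m3)
f3
#> EIRM fit 'm3' (MML, 41 GH nodes)
#>   persons 573, cells 6303, df 19, deviance 5672.8, AIC 5710.8, BIC 5839.1
#>   person variance 2.63 (SD 1.62)
#>                       ...
#> alcohol_no               1.60e-05   *** -0.91***(0.21)
#> sensation_seeking        2.88e-13   ***  0.60***(0.08)
#> gender_female:alcohol_no 2.00e-04   ***  1.36***(0.37)
```

The person variance drops from 3.27 to 2.63 as covariates absorb part
of the individual differences. At this sample size the recovered
effects sit near the generating truths (non-drinker −0.76, sensation
seeking 0.55, gender×alcohol 0.92): sensation seeking is the dominant
personality effect, and non-drinkers show lower latent SUD levels.
`run_ladder()` produces the full comparison table and
`dif_scan()`/`dif_table()` the DIF report; `pipeline_report()` writes
every table as CSV + JSON with the echoed configuration.

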