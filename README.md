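# confbias

Confounder adjustment only removes bias if the confounder's
relationships are modelled correctly.  In observational studies it is
routine to check linearity of the exposure–outcome effect, but rarely of
the **confounder–exposure** and **confounder–outcome** associations.
When a truly non-linear association is entered into an adjustment model
as linear — "misspecified" — the adjustment can *introduce* bias
(residual confounding) instead of removing it.  `confbias` is a toolkit
for epidemiologists and biostatisticians to quantify that bias by Monte
Carlo simulation, and to avoid it in their own analyses with flexible
functional forms and linearity diagnostics.

## The model

A standard-normal confounder *Z* and its square *C = Z²* confound the
effect of a binary exposure *X* on a continuous outcome *Y*:

    P(X = 1 | Z, C) = 1 / (1 + exp(−(i₄ + θ₁Z + θ₂C)))
    Y = i₅ + γ₁X + γ₂Z + γ₃C + ε,   ε ~ N(0, σ²)

so both associations are quadratic in *Z*.  An analysis that adjusts for
*Z* alone (omitting *C*) misspecifies the functional form.  Four
estimators of the exposure effect γ₁ are implemented:

| method | adjusts via | must be correctly specified |
|---|---|---|
| multivariable regression | outcome model `Y ~ X + confounders` | confounder–outcome |
| PS covariate adjustment | `Y ~ X + PS` | confounder–exposure (and PS–outcome) |
| stabilized IPW | weighted `Y ~ X`, weights `p/PS`, `(1−p)/(1−PS)` | confounder–exposure |
| double-robust (DR) | stabilized-weighted `Y ~ X + confounders` | either one |

Performance per simulation condition is summarized by the mean estimate,
the absolute bias AB = |mean − γ₁| and the relative bias RB = AB/|γ₁|.
Flexible bases — quantile dummies, polynomial terms, linear splines and
restricted cubic splines (`rcs()`) — model non-linear associations in
real analyses, and `assess_linearity()` tests whether that is needed.

## Worked example

Generate one dataset at the headline settings (n = 500, all confounder
coefficients 0.59, true effect γ₁ = 0.59), check linearity, and estimate
the effect four ways:

```r
library(confbias)
p <- sim_params(n = 500, theta1 = 0.59, theta2 = 0.59,
                gamma2 = 0.59, gamma3 = 0.59, seed = 1)
d <- generate_dataset(p)

assess_linearity(d$Z, d$Y)
#> Linearity diagnostic (nonlinear_term, continuous response)
#>   statistic = 393.9, p = 5.495e-65  ->  nonlinear_suspected (alpha = 0.05)
#>   coefficients beyond the linear term:
#>   pow2
#> 0.6409

adjust_effect(Y ~ X, d, method = "all")
#> Multivariable regression analysis
#>   exposure effect: 0.6570  (SE 0.1005, 95% CI 0.4600 to 0.8539)
#> Covariate adjustment using the PS
#>   exposure effect: 0.6118  (SE 0.1127, 95% CI 0.3910 to 0.8327)
#> Stabilized IPW
#>   exposure effect: 0.5870  (SE 0.1960, 95% CI 0.2028 to 0.9713)
#> DR estimation
#>   exposure effect: 0.5910  (SE 0.1008, 95% CI 0.3933 to 0.7886)
```

The quadratic term of *Z* is strongly significant (its true coefficient
is γ₃ = 0.59; the diagnostic estimates 0.64), so linear-only adjustment
is inadvisable.  With the correct terms `~ Z + C` all four estimates are
near the truth 0.59.

Now misspecify the confounder–outcome association (scenario 2: the
outcome model gets only `Z`) and average over 200 replications:

```r
run_condition(condition_spec(scenario = 2, n = 500, effect_size = 0.59,
                             reps = 200, master_seed = 1))
#> Condition: scenario 2, n = 500, effect size 0.59, true effect 0.59, 200 reps
#>         method mean_estimate     ab     rb  mc_se n_converged
#>  multivariable        0.9917 0.4017 0.6808 0.0083         200
#>   ps_covariate        0.5972 0.0072 0.0122 0.0067         200
#>            ipw        0.6418 0.0518 0.0879 0.0190         200
#>             dr        0.6455 0.0555 0.0941 0.0103         200
```

The multivariable estimate (which relies on the outcome model) is biased
upward by ~68% of the true effect; PS covariate adjustment, which relies
on the correctly specified propensity model, stays unbiased; IPW and DR
show only their finite-sample bias.  `run_grid()` runs the full design —
4 scenarios × 3 sample sizes × 6 effect sizes = 72 conditions — and
`assemble_table()` formats any slice of it.

A command-line interface is installed as `exec/confbias` with verbs
`simulate`, `analyze` (adjusted estimates for a CSV dataset, linear and
spline-based side by side) and `diagnose` (linearity reports per
confounder); run `confbias --help` for flags.

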