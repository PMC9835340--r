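---
title: "Quantifying bias from misspecified confounder functional forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bias from misspecified confounder functional forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confbias)
```

## The problem

A confounder is a common cause of an exposure and an outcome; adjusting
for it is how observational studies approximate the average treatment
effect $E[Y(1) - Y(0)]$.  Every adjustment method, however, encodes the
confounder through one or two working models — an outcome regression, a
propensity (exposure) model, or both — and those models usually assume
the confounder enters *linearly*.  If the true association is
non-linear, the "adjusted" estimate can be more biased than helpful.
`confbias` makes this failure mode measurable: it pairs the four
classical estimators with a data-generating process in which the
non-linearity is known exactly, so the bias of any
specification choice can be computed by simulation.

## Data-generating process

One confounder $Z \sim N(0,1)$ and its square $C = Z^2$ drive both the
binary exposure and the continuous outcome:

$$P(X=1 \mid Z, C) = \operatorname{logit}^{-1}(i_4 + \theta_1 Z + \theta_2 C),
\qquad
Y = i_5 + \gamma_1 X + \gamma_2 Z + \gamma_3 C + \varepsilon,\;
\varepsilon \sim N(0, \sigma^2).$$

Defaults are $i_4 = i_5 = 0$ and $\sigma = 1$: zero intercepts keep the
exposure prevalence near one half for small coefficients, and unit
noise puts the outcome on a standardized scale, so the coefficient
values 0.14 / 0.39 / 0.59 can be read as small / medium / large
standardized effects.  The true exposure effect is $\gamma_1 = 0.59$
(large) throughout the default design; the confounder coefficients vary
jointly ($\theta_1 = \theta_2 = \gamma_2 = \gamma_3 =$ the condition's
effect size), including negative values.  All parameters are
configurable through `sim_params()`, and `condition_spec()` additionally
allows decoupling $\gamma_2, \gamma_3$ from the joint effect size and
shrinking $\sigma$ towards zero — the noiseless limit used by the
exactness tests.

What this generator emulates is the canonical single-confounder,
quadratic-misspecification setting; what it deliberately does not
emulate is most of the mess of real data — multiple correlated
confounders, measurement error in the confounder, unmeasured
confounding, colliders, non-quadratic non-linearities, heteroskedastic
or non-normal outcome noise, and rare exposures.  A method passing the
simulation checks is therefore demonstrably correct *for this
mechanism*, not certified for any real dataset.

## The four estimators

With correct specification meaning "both $Z$ and $C$ in the model" and
misspecification meaning "$Z$ only":

* **Multivariable regression** regresses $Y$ on $X$ and the confounder
  terms; it needs the confounder–outcome association right.
* **Covariate adjustment using the propensity score** first estimates
  $PS = P(X=1 \mid \text{terms})$ by logistic regression, then
  regresses $Y$ on $X$ and the $PS$; it needs the propensity model
  right, plus a linear $PS$–outcome association (which holds in this
  design and can be relaxed through `ps_transform`).
* **Stabilized IPW** weights subjects by $p/PS$ (exposed) or
  $(1-p)/(1-PS)$ (unexposed), with $p$ the sample exposure proportion,
  then regresses $Y$ on $X$ alone; it needs the propensity model right.
  It is a large-sample technique: even correctly specified it carries
  finite-sample bias that the simulations show shrinking as $n$ grows.
* **Double-robust estimation** combines both: a stabilized-weighted
  regression of $Y$ on $X$ and the confounder terms, consistent if
  either working model is correct.

`adjust_effect()` is the single entry point; the scenario presets
(`scenario_spec(1:4)`) encode the four correct/misspecified
combinations of the two term lists.

## Numerical choices

* Linear and weighted-linear fits use QR least squares (`stats::lm`);
  logistic fits use iteratively reweighted least squares (`stats::glm.fit`)
  with convergence tolerance $10^{-8}$ and at most 100 iterations.
  Separation or a degenerate exposure is reported as
  `converged = FALSE` with a warning and the replication is recorded
  with its flag; non-converged replications are dropped from condition
  means with their count reported.
* Propensity scores are clipped into $[10^{-10}, 1-10^{-10}]$ purely
  for numerical safety.  No weight truncation or trimming is applied —
  stabilization is the only variance-control device — but `adjust_ipw()`
  warns when the largest weight exceeds 10 times the 99th-percentile
  weight.
* Variances: classical OLS covariance for unweighted fits; HC0
  heteroskedasticity-robust sandwich covariance (via the **sandwich**
  package) for the weighted estimators, the conventional choice for
  IPW-type estimators whose weighted residuals are heteroskedastic by
  construction.  Intervals use normal quantiles.  This is a reporting
  choice only; no simulation summary depends on it.
* Constant or collinear design columns are dropped with a warning
  rather than erroring, so degenerate cases (e.g. a constant propensity
  score under a null model) gracefully collapse to the unadjusted
  comparison.

## Randomness and reproducibility

Each replication's seed is derived deterministically from the master
seed, the sample size, the effect size and the replication index — and
*not* from the scenario.  Scenarios therefore analyse identical
datasets and differ only in their term lists, which removes a source of
between-scenario Monte Carlo noise and makes every condition
reproducible in isolation (and parallelizable in principle).  Two runs
with the same master seed are bit-identical.

## Simulation summaries

Per condition (scenario × n × effect size) and method, `run_condition()`
reports the mean estimate over converged replications, the absolute
bias $AB = |\bar{\hat\gamma}_1 - \gamma_1|$, the relative bias
$RB = AB / |\gamma_1|$, and the Monte Carlo standard error of the mean.
AB is computed from the mean of the estimates, not as a mean of
absolute errors — the only reading consistent with reporting mean, AB
and RB as a coherent triplet — and RB uses $|\gamma_1|$ so
negative-effect conditions stay nonnegative.  The mc\_se column is
reported although classical presentations omit it, because it is the
principled tolerance for judging whether a deviation from a reference
value is Monte Carlo noise.  The full default grid is
4 scenarios × 3 sample sizes (200, 500, 1000) × 6 effect sizes
(±0.14, ±0.39, ±0.59) = 72 conditions at 1000 replications each;
`run_grid()` accepts any sub-axes, and `assemble_table()` formats a
sample-size/sign slice as method-within-scenario rows with
(mean, AB, RB) triplets rounded to 4 decimals.

## Flexible functional forms and diagnostics

For real analyses, where the truth is unknown, the package provides the
standard repair kit: quantile-based dummy categorization (reference =
lowest group), raw polynomial terms, linear splines (truncated-power
hinge basis) and restricted cubic splines.  The RCS basis is the
truncated-power restricted form scaled by $(t_k - t_1)^{-2}$, linear
beyond the boundary knots; with $k$ knots it contributes $k-2$
non-linear columns.  Default knot placement is at the 10th/50th/90th
percentiles for 3 knots (5/35/65/95 for 4, 5/27.5/50/72.5/95 for 5) —
the standard practice when no substantive cut points exist.  All bases
are deterministic in their inputs and usable directly inside model
formulas (`~ rcs(Z, 3)`, `~ dummy(fitness, 4)`).

`assess_linearity()` implements the two non-visual diagnostics: adding
non-linear terms and testing them (F test for continuous responses,
likelihood-ratio test for binary), or categorizing the variable and
testing the saturated category fit against a linear-in-group-index fit.
The verdict threshold defaults to $\alpha = 0.05$, the conventional
significance threshold; the per-category coefficients are returned so a
non-monotone (e.g. U-shaped) pattern can be inspected directly.  A
scatterplot is the third classical check; it is left to the user's
plotting, as only the two test-based checks yield a programmatic
verdict.

## Design decisions worth recording

* The package follows the classic modelling-package shape: one fitting
  function returning a classed object with `print`/`summary`/`coef`/
  `confint`/`residuals` methods, with the simulation engine layered on
  top.  `predict`/`simulate` methods are not provided: the estimand is
  a single coefficient, and dataset simulation is `generate_dataset()`.
* Exact recovery on noiseless data holds for all four estimators only
  when the confounder–outcome coefficients are zero (otherwise the
  outcome is outside the span of the IPW and PS-covariate working
  models even without noise); the exactness tests therefore set
  $\gamma_2 = \gamma_3 = 0$, while multivariable and DR exactness is
  also exercised under full quadratic confounding.
* $p$ in the stabilized weights is the estimated marginal exposure
  proportion, not a fixed 0.5.
* Test and example problem sizes: moment checks use $10^5$–$10^6$
  draws; parameter-recovery checks use $n$ of a few thousand with
  3-standard-error tolerances; the full-scale grid checks use the
  design's own 1000 replications at $n = 500$, with supporting
  trend checks (bias vs effect size, bias vs $n$) at 1000 replications
  on single-method conditions.  Reference comparisons use fixed
  tolerances of 0.01 for theory-forced unbiased cells and 0.03 —
  roughly $3\sqrt{2}\,\mathrm{mc\_se}$ for two independent Monte Carlo
  runs of this size — for biased cells.

## Known limitations

Simulation mode generates exactly one confounder and its square;
multiple or differently shaped confounders are analysis-mode territory.
PS matching and stratification are out of scope, as are penalized
smoothers, GAMs and fractional polynomials.  Confidence intervals for
the weighted estimators use the HC0 sandwich and normal quantiles;
bootstrap intervals are not implemented.  IPW's finite-sample bias
means its simulation means should be judged against the sample-size
trend, not against the truth at small $n$.
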