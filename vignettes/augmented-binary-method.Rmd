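---
title: "The augmented binary method for composite responder endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The augmented binary method for composite responder endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augbin)
```

## The problem

Many trials define their primary endpoint as *responder / non-responder*,
where response requires a continuous measurement to cross a threshold
(tumour diameters shrinking by at least 30%, HbA1c at most 6.5%, ...)
together with a binary criterion (no new lesions, no rescue therapy).
The conventional analysis dichotomises first and then compares responder
proportions between arms.  Dichotomisation throws away the information in
how far each patient sits from the threshold; for a single normal
endpoint the best possible cut (the median) already inflates the required
sample size by a factor of $\pi/2 \approx 1.57$, and any other cut is
worse (`dichotomisation_cost_analytic()`).

The augmented binary method keeps the endpoint definition exactly as the
protocol states it, but estimates the response probabilities from a joint
model of the components instead of from raw counts.

## The model

For subject $i$ with arm indicator $z_i \in \{0,1\}$, continuous
component $y_i$ and binary component $b_i$:

$$y_i \mid z_i \sim N(\alpha + \theta z_i,\ \sigma^2), \qquad
  b_i \mid y_i, z_i \sim \text{Bernoulli}\{\Lambda(\gamma_0 + \gamma_1 z_i
  + \gamma_2 y_i)\},$$

with $\Lambda$ the inverse logit.  $\gamma_2$ lets the probability of
meeting the binary criterion depend on the continuous outcome — in
oncology, patients whose lesions shrink are also less likely to develop
new ones.  Setting `gamma2_free = FALSE` restricts to independent
components.  This logistic-dependence formulation is the simplest joint
model that makes the components non-independent; richer latent-variable
couplings exist, and the fitted-model surface here is deliberately
agnostic about them.

A responder rule $R$ (threshold $\tau$, direction, plus the binary
criterion) never enters the likelihood.  It enters only at the inference
step, through

$$p(z) = \int_R N(y;\ \alpha + \theta z, \sigma^2)\,
  \Lambda(\gamma_0 + \gamma_1 z + \gamma_2 y)\, dy,$$

so the same fit serves any threshold.  The treatment effect is reported
as $p(1) - p(0)$ (with a Wald test) and as the odds ratio.

### Inference

`fit_joint_model()` maximises the joint likelihood.  Two structural facts
shape the implementation:

* With complete data — and, more generally, whenever no record has a
  missing $y$ together with an observed $b$ — the likelihood factorises
  exactly into the normal sub-model and the logistic sub-model.  The MLE
  is then the closed-form normal fit plus the IRLS logistic fit, which is
  also why the fitted sub-models agree with standalone `lm`/`glm` fits to
  numerical precision.
* A record with observed $b$ but missing $y$ couples the two blocks: its
  contribution is $\Pr(b \mid z)$ with $y$ integrated out (40-node
  Gauss–Hermite quadrature).  In that case the full six-parameter
  likelihood is maximised by BFGS on a log-$\sigma$ parameterisation,
  started from the factorised estimates.  Fitting is deterministic.

Either way, the covariance matrix is the inverse of the observed
information of the *full* joint log-likelihood, computed by central
differences with relative step $10^{-5}$ and symmetrised.  Standard
errors for $p(0)$, $p(1)$, their difference and the log odds ratio come
from the delta method with numerically differenced gradients.
Confidence intervals are formed on the logit scale per arm (respecting
the $[0,1]$ range), the identity scale for the difference, and the log
scale for the odds ratio.

Missingness is assumed ignorable given arm and the observed components.
Subjects missing one component are *retained* by the augmented analysis
through marginalisation, whereas `binary_analysis()` must drop every
subject whose responder status is undetermined — this asymmetry is one of
the method's practical advantages and is deliberately preserved.

### Response weights

The method can be read as replacing each patient's 0/1 responder status
with a weight in $[0,1]$ that is smooth in the distance from the
threshold.  No canonical formula exists for display purposes, so
`response_weights()` offers two variants and documents the default:

* `"gated"` (default): $\Phi\{(y-\tau)/\hat\sigma\}$ for patients meeting
  the binary criterion, 0 otherwise.  The fitted residual SD is the
  natural smoothing scale: a patient a fraction of $\hat\sigma$ below
  threshold — who may owe that position to measurement error — keeps a
  weight near 0.5 instead of being declared a hard 0.
* `"model_based"`: the hard binary gate is replaced by the fitted
  logistic probability, giving a fully model-based weight.

Missing components always receive model-based predictive weights.

### Normality checking

The normal assumption on $y$ is the method's main vulnerability.
`estimate_boxcox()` maximises the Box–Cox profile log-likelihood over the
grid $\lambda \in [-3, 3]$ in steps of 0.01, including the Jacobian term,
profiling about *per-arm* means so that a real arm effect is not mistaken
for skewness.  `fit_joint_model(..., boxcox = "auto")` applies the
estimated transform before fitting and `augbin_analysis()` maps the rule
threshold onto the same scale.  Note $\lambda$ is weakly identified when
the coefficient of variation is small (data far from zero relative to
their spread); that is a property of the transform family, not of the
estimator.

## The synthetic-trial generator

`simulate_trial()` draws from exactly the model above: normal $y$ with an
arm shift, logistic $b$ given the *generated* $y$ (so a later-masked
value still influenced $b$), then independent MCAR masking of each
component.  Streams are derived from `(seed, replicate)`, so every
experiment is bit-reproducible, and the power machinery shares each
replicate's draws across methods and across sample sizes (common random
numbers).

What the generator does *not* emulate: skewed or heavy-tailed continuous
components (except via the explicit log-normal fixture), informative
missingness, baseline covariates, multiple timepoints, or more than two
components.  A passing simulation suite therefore certifies the method
*under its own assumptions*; it says nothing about robustness to model
misspecification beyond the Box–Cox route.

## The efficiency experiments

The documented effect scenario is $\alpha = 0$, $\theta = 0.4$,
$\sigma = 1$, $\gamma_0 = 2$, $\gamma_1 = 0$, $\gamma_2 = 0.5$, responder
$= (y \ge 0) \wedge (b = 1)$, $n = 100$ per arm, two-sided 5% level.
$\theta = 0.4$ SD puts the augmented analysis near 80% power — the region
where trials are actually sized; $\gamma_0 = 2$ gives a realistic ~88%
rate of meeting the binary criterion; the threshold sits at the control
median, the most favourable cut, making the measured gain conservative.
The matching null scenario sets $\theta = \gamma_1 = 0$.

`effective_sample_size_gain()` answers "how many more subjects would the
binary analysis need to match the augmented analysis' power?" by
estimating the target method's power at $n$, then inverting the reference
method's power curve over $[n, 10n]$ by integer bisection.  Monte-Carlo
jitter is controlled three ways: common random numbers across $n$ (each
replicate draws $10n$ subjects per arm once and analyses the first $n$),
isotonic regression over the evaluated power-vs-$n$ points before each
bracketing decision, and linear interpolation inside the final bracket.
The same machinery with the binary criterion forced on
($\gamma_0 = 40$) and a `"ttest"` target reproduces the classical
single-endpoint dichotomisation cost by simulation, which can be checked
against the closed form $p(1-p)/\phi\{\Phi^{-1}(p)\}^2$.

Replicate counts default to 500–1000: large enough that the inequalities
of interest (gain above 30%, type-I error within three Monte-Carlo SEs of
5%, narrower mean CI) are stable, small enough for a desk-scale rerun.
Fit failures count as non-rejections — conservative for power claims —
and are reported; they are excluded from CI-width averages.

## Numerical choices and degenerate inputs

* Quadrature for $p(z)$: adaptive (`stats::integrate`) to absolute
  tolerance $10^{-8}$, with limits clipped to $\mu \pm 12\sigma$ — the
  truncated mass ($<2\times10^{-32}$) is negligible, and the clipping
  prevents the adaptive rule from missing a narrow bump inside an
  infinite interval when $\tau$ is extreme.
* Threshold comparisons are inclusive ($y = \tau$ responds), matching the
  $\ge$/$\le$ wording of clinical definitions, and tested explicitly.
* Complete separation in the logistic sub-model (including all observed
  $b$ identical) yields `converged = FALSE` with a `separation` flag
  rather than silently divergent estimates; `augbin_analysis()` refuses
  to proceed.  A singular observed information matrix raises an error
  suggesting `gamma2_free = FALSE`.
* Zero cells in the binary analysis take the Haldane–Anscombe 0.5
  correction for the odds ratio (flagged), or raise an error when the
  correction is disabled.
* Two identical arms give a treatment effect of zero to optimizer
  tolerance (about $10^{-10}$), not to the last bit: the IRLS and BFGS
  stopping rules, not the algebra, set the floor.

## Limitations

Single timepoint, one continuous and one binary component, no covariate
adjustment beyond arm, frequentist Wald inference only.  The Wald test on
the difference is slightly conservative at $n = 100$ per arm in the
simulations shipped with the package; profile-likelihood or score
intervals would be natural refinements.  Time-to-event responder
definitions and "m of k" composite rules are out of scope.
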