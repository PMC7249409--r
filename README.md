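# augbin — augmented binary analysis of composite responder endpoints

Trials in oncology, rheumatology, diabetes and many other areas report a
*composite responder endpoint*: a patient is a responder when a continuous
measurement crosses a threshold (tumour diameters shrink by ≥ 30%, HbA1c
≤ 6.5%, ...) **and** a binary criterion holds (no new lesions, no rescue
therapy).  The standard analysis dichotomises first and compares responder
proportions, discarding the information in how far each patient sits from
the threshold.  `augbin` is for trial statisticians who want to keep the
protocol's responder definition but analyse it efficiently.

## The method

The package fits a joint model to the two components,

$$y \mid z \sim N(\alpha + \theta z,\ \sigma^2), \qquad
  b \mid y, z \sim \mathrm{Bernoulli}\{\Lambda(\gamma_0 + \gamma_1 z + \gamma_2 y)\},$$

($z$ = arm, $\Lambda$ = inverse logit), by maximum likelihood, and derives
each arm's response probability from the fitted model,

$$p(z) = \int_R N(y;\ \alpha + \theta z, \sigma^2)\,
  \Lambda(\gamma_0 + \gamma_1 z + \gamma_2 y)\,dy,$$

where $R$ is the responder region of the rule (e.g. $y \ge \tau$).
Standard errors for $p(0)$, $p(1)$, the difference and the odds ratio use
the delta method through the inverse observed information.  The endpoint
definition is untouched — only the estimator changes — yet the confidence
intervals are markedly narrower and the power higher, because patients
near the threshold are no longer treated as hard 0/1 outcomes.  Subjects
with one missing component are retained via likelihood marginalisation
instead of being dropped.  The classical binary analysis
(`binary_analysis()`) is always available as the comparator, and the
analytic cost of dichotomising a single normal endpoint,
$p(1-p)/\phi\{\Phi^{-1}(p)\}^2$ (≈ π/2 at the median cut), is exposed as
`dichotomisation_cost_analytic()`.

## Worked example

```r
library(augbin)

rule <- composite_rule(
  component_rule("at_least", 0, "standardised change from baseline"),
  description = "responder: improvement of at least 0 AND binary criterion met")

sc    <- scenario_config(n_per_arm = 100, seed = 5)   # default effect scenario
trial <- simulate_trial(sc)                           # or read_trial_csv("trial.csv")

binary_analysis(trial, rule)
#> Binary analysis of composite responder endpoint
#>   control   p0 = 0.4400 (95% CI 0.3461, 0.5383)
#>   treatment p1 = 0.6000 (95% CI 0.5013, 0.6912)
#>   difference   = 0.1600 (SE 0.0697; 95% CI 0.0233, 0.2967)
#>   log OR       = 0.6466 (SE 0.2868; 95% CI 0.0845, 1.2087)
#>   Wald z = 2.294, two-sided p = 0.02178  (n0 = 100, n1 = 100)

augbin_analysis(trial, rule)
#> Augmented binary analysis of composite responder endpoint
#>   control   p0 = 0.4839 (95% CI 0.4062, 0.5625)
#>   treatment p1 = 0.6256 (95% CI 0.5478, 0.6975)
#>   difference   = 0.1417 (SE 0.0548; 95% CI 0.0342, 0.2492)
#>   log OR       = 0.5778 (SE 0.2266; 95% CI 0.1336, 1.0220)
#>   Wald z = 2.584, two-sided p = 0.009758  (n0 = 100, n1 = 100)
```

Both estimators see the same trial and the same responder rule.  The
augmented difference CI is 0.215 wide against 0.273 for the binary one —
a (0.215/0.273)⁻² − 1 ≈ 61% sample-size equivalent — and the p-value
drops accordingly.  `response_weights()` returns the per-patient fitted
weights behind the estimate; `fit_joint_model(..., boxcox = "auto")`
handles skewed components.

Simulation tools: `run_power_study()` (power, type-I error, CI width,
with common random numbers across methods) and
`effective_sample_size_gain()` (percent extra sample size the binary
analysis needs to match the augmented one, by power-curve inversion).

A command-line wrapper with `analyze`, `fit`, `simulate`, `power`, `ess`
and `fixture` subcommands is installed at
`system.file("cli", "augbin", package = "augbin")`; input is CSV with
header `id,arm,y,b` (empty cell = missing) plus a small YAML config — see
`?augbin_cli`.

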