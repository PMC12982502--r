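---
title: "Uncertainty-aware nitrogen-rate analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware nitrogen-rate analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Maize yield responds to fertilizer nitrogen up to a point and then
plateaus. Two rates matter to a grower: the agronomic optimum (AONR), where
expected yield is maximized, and the economic optimum (EONR), where the
marginal kilogram of grain exactly pays for the marginal kilogram of N.
Both are functions of a fitted response curve, and the curve itself is
uncertain — soil, weather and crop dynamics make the "right" rate for a
given season unknowable at planting. `onrisk` treats that uncertainty as
the object of interest: it fits the response curve by Bayesian MCMC,
carries the full posterior into the optimum rates, and asks what a grower
risks — and what society gains — when fertilizer rates are walked down in
stages.

## The yield model

For yield $y_{ij}$ at N rate $x_i$ in block $j$ of one site-year:

$$y_{ij} \sim \mathrm{Normal}(\mu_{ij}, \sigma_\varepsilon), \qquad
\mu_{ij} = \begin{cases}
\beta_0 + \tau_j + \beta_1 x_i - \beta_2 x_i^2 & x_i < \beta_1/(2\beta_2)\\
\beta_0 + \tau_j + \beta_1^2/(4\beta_2) & \text{otherwise.}
\end{cases}$$

The breakpoint $\beta_1/(2\beta_2)$ is where the quadratic arm peaks, so
the mean is continuous there and the plateau equals the quadratic's
maximum. Crucially, the breakpoint inside the likelihood is each MCMC
draw's *own* $\beta_1/(2\beta_2)$, never a point estimate: the location of
the plateau is uncertain and that uncertainty must propagate.

Priors are gamma on $\beta_0, \beta_1, \beta_2, \sigma_\varepsilon$
(positive support; per-state hyperparameter tables, see below), block
effects $\tau_j \sim \mathrm{Normal}(0, \sigma_b)$ with
$\sigma_b \sim \mathrm{Uniform}(0, 5000)$. The grain-N model
(`fit_grain_n()`) has the same structure on grain N content (kg ha⁻¹)
with fixed wide uniform priors — $\beta_0 \sim U(0,300)$,
$\beta_1 \sim U(0,5)$, $\beta_2 \sim U(0,2)$, both SDs $U(0,1000)$ — and a
form rule: fit the plateau form; if the posterior-mean breakpoint exceeds
the largest tested rate (the plateau was never observed), refit as a plain
quadratic. Sampling is Gibbs/slice MCMC via JAGS (`rjags`); the reference
settings are 4 chains × 60,000 iterations, 30,000 warm-up, thinning 10
(12,000 retained draws), with `mcmc_profile("fast")` (4 × 5,000, 2,000
retained) for simulation studies and tests.

### Initial values and convergence

Chains are started from a least-squares quadratic-plateau pre-fit
(breakpoint profiled on a grid; the model is linear in the coefficients
once the breakpoint is fixed), jittered multiplicatively per chain. This
matters in the near-noise-free regime, where the posterior is a sharp
ridge a random prior draw essentially never finds. Convergence is judged
by a rank-normalized split-$\hat R$ (`split_rhat()`): chains are halved,
draws replaced by normal scores, and the classic between/within ratio
computed on the result; the value is floored at 1. The pass threshold is
1.02, applied to every parameter *and* to the derived AONR/EONR draws —
a site whose derived quantities have not converged is not a site you can
make rate recommendations from. Effective sample sizes come from `coda`.

One identifiability note: the block effects carry no sum-to-zero
constraint, so in the $\sigma_\varepsilon \to 0$ limit the intercept is
identified only jointly with the blocks' common shift,
$\beta_0 + \bar\tau$. The recovery tests assert exactly that combination;
$\beta_1$ and $\beta_2$ are unaffected.

## Prior elicitation and the shipped defaults

`elicit_hyperparameters()` implements the two-stage scheme: fit reference
trials with wide uniform priors, then moment-match each parameter's
pooled posterior mean $m$ and variance $v$ to
$\mathrm{gamma}(\alpha = m^2/v,\ \beta = m/v)$. The shipped per-state
defaults (`default_hyperparameters()`) were elicited from synthetic
reference trials generated by this package (`data-raw/`): three sites per
state with optima at the state centre ± 30 kg ha⁻¹ (centres 138–261
kg ha⁻¹ across the eight states, so site optima span 108–291 kg ha⁻¹) and
±15% curvature spread. Pooling draws across a state's sites makes the
priors carry between-site variability, not just one site's posterior
precision — with single-site elicitation the priors were tight enough to
dominate every later fit, which is not what a state-level prior should do.
These defaults are placeholders with realistic structure, not an elicitation
from any real historical dataset; supply your own table for real analyses.

## Derived quantities

Per retained draw (Monte-Carlo integration):

* $\mathrm{AONR} = \beta_1 / (2\beta_2)$;
* $\mathrm{EONR} = (\beta_1 - PR) / (2\beta_2)$, clamped at 0 in the rare
  draws where the sampled price ratio exceeds $\beta_1$ (a negative rate is
  physically meaningless; the clamp touches only pathological draws);
* the price ratio $PR$ (kg maize per kg N) is sampled once per posterior
  draw — coupled 1:1, not nested — from
  $\mathrm{gamma}(15.25, 2.856)$, the exact moment match of mean 5.34 and
  variance 1.87. (Strict matching gives 15.249/2.856; the commonly quoted
  rounding of the same computation, 15.2/2.8, is not an exact moment
  match — we keep the strict version.) A fixed scalar PR is supported for
  oracle checks.

All summaries use the linear-interpolation empirical quantile (type 7,
order statistics interpolated at $h = (n-1)p + 1$), fixed package-wide so
outputs are bit-reproducible. The 95% credible interval is the 0.025–0.975
quantile span; "relative width" is that span as a percent of the mean.

## Risk of staged reductions

`run_phases()` builds the reduction schedule: Phase I from E[AONR] to
E[EONR]; Phase II cases 1–4 from E[EONR] down to the 0.4, 0.3, 0.2, 0.1
quantiles of the EONR posterior; and a combined row from E[AONR] straight
to the target quantile (default 0.3, the conventional "safest case" —
configurable). For a reduction from rate $a$ to rate $b$, each draw's
population-level mean curve (block effect 0, no residual noise) is
evaluated at both *fixed* rates and the loss is $\mu_d(a) - \mu_d(b)$.
Because each draw's curve is non-decreasing, a draw registers a strictly
positive loss exactly when its own breakpoint exceeds $b$; the probability
of loss is the fraction of such draws (ties at zero count as non-loss).
Relative losses are quoted against expected yield at E[AONR] for Phase I
and the combined cut, and against expected yield at E[EONR] for the
Phase II cases. If a case's quantile rate exceeds E[EONR] (possible under
skew), the target is clamped at E[EONR] so every row is a genuine
reduction.

Sites enter this analysis only if every monitored $\hat R \le 1.02$ and
E[AONR] does not exceed the largest tested rate — otherwise the "optimum"
is an extrapolation artifact. `select_scenarios()` labels the retained
sites with the widest, median-closest and narrowest EONR credible
intervals A/B/C (ties broken lexically by site id).

## Environmental and social translation

For a reduction from rate $a$ to $b$, the N balance at each rate is
rate minus predicted grain N (per grain-N posterior draw, population
level). Expected emissions follow the nitrogen-balance models
$E[\mathrm{N_2O\text{-}N}] = e^{0.339 + 0.0047\,\mathrm{bal}}$ and
$E[\mathrm{NO_3^-\text{-}N}] = e^{2.459 + 0.0061\,\mathrm{bal}}$
(kg ha⁻¹). Uncertainty is propagated by replacing each expectation $E$
with a draw from $\mathrm{gamma}(E^2/v,\ E/v)$ — same mean, literature
variance $v$. The shipped `var_n2o = 1` and `var_no3 = 36` (kg ha⁻¹)² are
order-of-magnitude placeholders and the package warns when they are used;
expected *differences* between rates are insensitive to them by linearity,
only the spread of the propagated draws depends on them. Negative
propagated differences are kept as-is — truncation would bias the benefit
upward.

Monetization: avoided N₂O-N × 44/28 (to N₂O mass) × 265 kg CO₂-e/kg
(100-yr GWP, no feedbacks; configurable) plus avoided manufacture CO₂
(ΔN × 17/14 × 2.16 kg CO₂ per kg NH₃, Haber–Bosch), converted kg → t,
priced at 50 \$/t CO₂-e; plus avoided leaching at 18.54 \$/kg N.
`scale_to_region()` multiplies per-hectare values by state planted areas
(shipped: approximate 2019–2023 USDA-NASS averages for the eight Corn
Belt states, ~23.5 M ha total) under the stated assumption that all
states follow the same response simultaneously — errors are then perfectly
correlated and the SE scales linearly with summed area. The reported
"SE" is the SD of the propagated draw distribution, labelled as such.

A known discrepancy: regional social-benefit totals of a few hundred
million dollars reported in the literature for this system cannot be
reproduced from the same quoted prices, per-hectare reductions and
areas — the leaching term alone exceeds them. `onrisk` computes the
benefit equation literally, so its regional totals come out several-fold
higher; treat absolute scaled dollars with caution and the per-hectare
decomposition as the reliable quantity.

## The trial simulator

`simulate_site()` draws complete randomized-complete-block trials: 8 rates
(0–315 kg ha⁻¹ in 45 kg steps) × 4 blocks = 32 plots by default, yields
from the quadratic-plateau surface plus Normal block effects and residuals,
grain N from its own (default plateau-form) surface, truncated to be
non-negative and below yield. Yields are generated directly on the
155 g kg⁻¹ moisture basis; moisture adjustment is pre-processing outside
the model. One master seed splits into per-site streams
(`derive_seed()`), so multi-site batches are reproducible site by site.

`scenario_presets()` fixes three configurations spanning low to high
optimum-rate uncertainty. Their curvatures and slopes put the generating
optima near 254, 205 and 174 kg ha⁻¹ with Phase I reductions (mean
PR / 2β₂) near 22, 19 and 14 kg ha⁻¹; residual SDs were set once at 2600,
1000 and 400 kg ha⁻¹ so the *fitted* AONR relative widths land near 52%,
43% and 33% — ordered A > B > C and inside the 27–87% band observed across
real Corn Belt sites, though not reaching its extremes (those arise from
near-linear responders that the reliability filter excludes anyway).

What the simulator does *not* emulate: weather- and soil-driven curve
shapes (every site is exactly quadratic-plateau, so model misspecification
is untested), spatial within-field variability, skewed or heteroscedastic
residuals, manure or split applications, and site-to-site correlation
within a year. Passing tests therefore certify the statistical machinery
under the model's own assumptions, not robustness to real-data violations
of them.

## Problem sizes and numerical choices

The test suite runs the fast MCMC profile almost everywhere; the
calibration study uses 100 simulated sites with truths drawn from the
fitting priors (the regime where 95% intervals cover at exactly 95% in
expectation), and the low-noise bias check uses 12 sites under wide
uniform priors. The acceptance script fits the three presets at the full
reference settings. Divisibility of `(n_iter - n_warmup)` by `thin` is
enforced so retained-draw counts are exact; all file interfaces are plain
CSV/JSON.

## Limitations

Beyond the simulator's scope above: single-site fits only (no multi-site
hierarchical pooling, no covariates); two mean forms only; the
environmental optimum N rate is out of scope; NOₓ and NH₃ benefits are
excluded, so social benefits are conservative in that respect; and the
shipped hyperparameters, emission variances and planted areas are
defaults to be replaced in any real application.
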