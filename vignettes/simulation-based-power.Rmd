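---
title: "Simulation-based power for confounded survival studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power for confounded survival studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortpower)
```

## Why simulate?

Analytic power formulas for survival outcomes assume away the features
that make real cohort studies hard: confounding, administrative
censoring, and hazards that change over follow-up. When all three are
present there is no closed form for the power of a Wald test on an
adjusted hazard ratio, so `cohortpower` estimates it the direct way:
state the data-generating mechanism (DGM) explicitly, replicate the
whole study — generate, fit, test — a few thousand times, and count
rejections. The same replication machinery yields type-I error under a
null variant of the DGM, the full sampling distribution of the estimated
hazard ratio, and the variability of estimated survival curves.

## The data-generating mechanism

A scenario is drawn causally in three steps per subject:

1. **Confounder** `z ~ Bernoulli(p_z)` — in the worked example, an
   indicator of being older than 80 years, with `p_z = 0.6`.
2. **Exposure** `x | z ~ Bernoulli(expit(logit(p_x0) + ψ z))` — physical
   activity, with `p_x0 = 0.5` and `ψ = log(1/3)`: older subjects have
   one third the odds of being active.
3. **Outcome** — a Weibull proportional-hazards time-to-death with
   hazard `h(t|x,z) = γ t^{γ-1} exp(β0 + β1 x + β2 z)`.

`z` causes both `x` and the outcome, so the marginal association between
`x` and death is confounded; only the adjusted model recovers `β1`.

The latent time comes from inverse-transform sampling: one uniform draw
`u` per subject is read directly as a survival probability and the
survival function is solved for `t`,

$$ t = \left( \frac{-\log u}{\exp(\beta_0+\beta_1 x+\beta_2 z)} \right)^{1/\gamma}. $$

(Since `U` and `1−U` are both uniform, drawing `u` and treating it as
`S(t)` is distributionally identical to drawing the CDF value; we use
one uniform stream per variable — `z`, then `x`, then `u` — in a fixed
order, so a cohort is bit-reproducible given the scenario and a seed.)

Follow-up is administratively censored at `τ` years: observed time is
`min(t, τ)` and the event indicator is 1 exactly when the latent time
falls strictly inside the window. Strict inequality (rather than `≤ τ`)
keeps the invariant "censored if and only if time equals `τ`" exact; the
two conventions differ only on a probability-zero event. There is no
random censoring, no delayed entry, and no ties by construction — time
is continuous and every subject enters at 0.

## Parameters of the worked example, with units

| parameter | meaning | default | why |
|---|---|---|---|
| `p_z` | P(older than 80) | 0.6 | stated cohort composition ("about 60%" implemented as exactly 0.6) |
| `p_x0` | P(active \| younger) | 0.5 | stated baseline exposure prevalence |
| `ψ` | log odds-ratio of exposure per `z` | log(1/3) | older subjects have 67% lower odds of activity |
| `β0` | log baseline mortality rate, per year | log(7/1000) | 7 deaths per 1000 person-years among young, inactive |
| `β1` | log HR for activity | log(0.8) | the 20% mortality reduction the study should detect |
| `β2` | log HR for age | log(4) | strong confounder–outcome effect |
| `γ` | Weibull shape, unitless | 1.1 | slightly increasing hazard with age over follow-up |
| `τ` | follow-up, years | 10 | administrative end of study |
| `n` | cohort size | 5000 | gives ~1005 expected deaths and ~86% power |
| `α` | two-sided test level | 0.05 | conventional |

All parameters are stored at full double precision (`log(7/1000)`, not
the printed −4.962). `expected_events()` evaluates the design in closed
form — because both covariates are binary and censoring is purely
administrative, every expectation is a sum over the four covariate
patterns and no quadrature is ever needed:

```{r}
sc <- activity_mortality_scenario()
pattern_table(sc)
expected_events(sc)
```

## Fitting and numerical choices

`fit_weibull_ph()` maximizes the right-censored Weibull log-likelihood

$$ \ell = \sum_i d_i\{\log\gamma + (\gamma-1)\log t_i + lp_i\} - e^{lp_i} t_i^\gamma $$

by Newton–Raphson with analytic gradient and Hessian.

* **Shape positivity** is structural: the optimizer works on
  `s = log γ`; the covariance is reported on the `(β, log γ)` scale.
* **Initialization**: `β0` starts at the exponential moment estimate
  `log(events / person-time)` with `β1 = β2 = 0`, `s = 0`. For
  realistic event rates this is inside the Newton attraction basin;
  fits on the worked example converge in about 5 iterations.
* **Convergence**: gradient max-norm `< 1e-8`, or relative
  log-likelihood change `< 1e-12` provided the gradient norm is below
  `1e-6`; at most 200 iterations, with step-halving whenever a full
  Newton step would decrease the likelihood. A fit that meets neither
  criterion is returned with `converged = FALSE` and downstream Wald
  summaries refuse it — non-convergence is never silent.
* **Degenerate inputs**: a cohort with zero events or a constant
  covariate is rejected up front with a specific error rather than
  producing an unstable fit.
* **Critical values** use the exact normal quantile (1.959964... at
  95%), never the rounded 1.96; p-values are kept at full precision and
  rounding is purely a display concern.
* **Ties**: none arise (continuous time), so no tie-breaking rule
  exists to choose.

The fitter was cross-checked against two independent routes: the
accelerated-failure-time parameterization of `survival::survreg`
(mapping `γ = 1/scale`, `β_PH = −β_AFT/scale`; agreement to 1e-6) and,
for `γ = 1` data with the shape held fixed, a Poisson GLM with a
log-person-time offset on the four aggregated covariate patterns
(agreement to better than 1e-3). The saturated per-pattern rates
(`exponential_pattern_mle()`) are deliberately kept as a separate
bookkeeping oracle: a three-parameter regression over four patterns is
not saturated, so its MLE matches the GLM route, not the raw
events/person-time ratios.

## The replication engine and seed discipline

`run_replications()` precomputes one substream seed per replicate from
the master seed (sampling without replacement from the 31-bit seed
space), so results are deterministic, independent of execution order,
and a replicate can be reproduced in isolation from its logged seed.
`"null"` mode changes exactly one thing in the generator — `β1 := 0` —
leaving the confounder and exposure models untouched, so type-I error is
evaluated under the same design that the power run uses. Non-converged
replicates are excluded from the rejection denominator *and* counted in
the output: silently including them would bias power, silently dropping
them would hide pathology. (None occur across the packaged scenario's
test runs; the accounting exists for harsher scenarios.)

Replicate counts default to 10,000 for power runs and 900 for
survival-curve ensembles, both overridable. The Monte Carlo standard
error `sqrt(p(1-p)/R)` is always reported next to any estimated
proportion.

Deliberate design choices where the design was open:

* Power and calibration runs **require** an explicit master seed rather
  than running unseeded; a reproducible stochastic run strictly
  dominates an irreproducible one.
* `calibrate_sample_size()` searches a user-supplied candidate grid and
  reports the smallest sufficient size or an explicit "none sufficient"
  outcome — no adaptive search, so the simulation budget is predictable.
* The CLI never overwrites an existing output without `--force`, and
  every run logs its version, resolved configuration and seeds.

## What the generator does and does not emulate

The synthetic cohorts reproduce the stated world of the worked example:
a single binary confounder, a single binary exposure, Weibull event
times, and administrative censoring only. Real cohort data add
loss-to-follow-up, continuous and multiple confounders, measurement
error, and entry staggering — none of which are modelled. A green test
therefore establishes that the *method* (fitting, testing, power
estimation) is correct under its assumed DGM, not that the worked
example's effect sizes are epidemiologically true, and not that the
power figure transfers to designs whose censoring or confounding
structure differs.

One printed anchor is intentionally not reproduced: the worked example's
unique seeded sample (974 deaths, HR 0.89, z = −1.52, p = .13) depends
on the RNG stream of the software that drew it. Under this package's
stream, seed 20230413 gives 956 deaths and HR 0.87 — distributionally
equivalent, numerically different. The tests therefore check the event
count against its closed-form 3-standard-error band (1005 ± 85) and
verify the Wald machinery reproduces the printed z and p when fed the
printed estimate and its back-derived standard error.

## Known limitations

* Power is Monte Carlo only; there is no closed-form fallback, by
  design, because none exists for this DGM.
* Power targets a single scalar coefficient (`β1`); joint tests are out
  of scope.
* No competing risks, frailty, time-varying exposures, or
  non-administrative censoring.
* The Weibull parameterization is fixed to the rate (proportional-
  hazards) form; accelerated-failure-time output is not provided.
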