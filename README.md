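# cohortpower

Monte Carlo design of time-to-event cohort studies: simulate cohorts from
an explicit confounded data-generating mechanism, fit the Weibull
proportional-hazards model by maximum likelihood, and estimate statistical
power, type-I error, and the sampling distribution of the hazard ratio by
replicating the whole generate–fit–test cycle.

It is aimed at epidemiologists and biostatisticians who want power and
sample-size calculations for survival outcomes where no closed form
exists — confounding, censoring, and a non-constant hazard all at once —
and at anyone teaching or learning how a single study relates to the
sampling distribution behind it.

## The model

Each synthetic cohort is drawn causally, confounder → exposure → outcome:

- confounder: `z ~ Bernoulli(p_z)`
- exposure: `x | z ~ Bernoulli(expit(logit(p_x0) + ψ·z))`
- outcome: Weibull proportional hazards,
  `h(t | x, z) = γ t^(γ−1) exp(β0 + β1·x + β2·z)`,
  so `exp(β0)` is the baseline event rate per year when `γ = 1`, and
  `exp(β1)`, `exp(β2)` are adjusted hazard ratios.

A latent time-to-event is drawn by inverse-transform sampling — one
uniform `u` per subject is treated as a survival probability, and
`t = (−log(u)/exp(lp))^(1/γ)` solves `S(t) = u`. Follow-up ends at a
fixed `τ` years (administrative censoring): subjects with latent time
beyond `τ` contribute time `τ` with event indicator 0.

The fitter maximizes the right-censored Weibull log-likelihood by
Newton–Raphson with analytic gradient and Hessian, optimizing `log γ` so
the shape stays positive; Wald z-tests and confidence intervals for the
hazard ratios come from the inverse observed information. Power is the
fraction of replicated studies whose two-sided Wald p-value for `β1`
falls below `α`.

## The packaged worked example

`activity_mortality_scenario()` describes a 10-year observational cohort
of 5000 older adults: about 60% are over 80 (`z`), younger subjects are
physically active (`x`) with probability 50% while older subjects have
1/3 the odds, baseline mortality is 7 deaths per 1000 person-years
(`β0 = log(7/1000)`), physical activity lowers the mortality hazard by
20% (`β1 = log(0.8)`), age quadruples it (`β2 = log(4)`), and the shape
is `γ = 1.1`.

## Worked example

```r
library(cohortpower)
run_cli(c("example", "--n-reps", "10000"))
```

prints (RNG fixed by the default seed 20230413):

```
== Design: closed-form expectations ==
Covariate-pattern table (joint probability, death by tau)
 z x joint_prob event_prob
 0 0       0.20     0.0844
 0 1       0.20     0.0681
 1 0       0.45     0.2971
 1 1       0.15     0.2457
expected deaths over 10 years: 1005.1

== Design: Monte Carlo power (10000 replicates) ==
Monte Carlo replication run (alternative mode, n = 5000, alpha = 0.05)
  replicates: 10000 requested, 10000 converged
  power = 0.8647 (MC SE 0.0034)
  mean events per study = 1004.8

== One seeded study (seed 20230413) ==
deaths in this sample: 956 of 5000
Weibull proportional-hazards fit: 5000 subjects, 956 events
              coef     se     hr
intercept  -4.9603 0.1173 0.0070
exposure   -0.1342 0.0742 0.8744
confounder  1.3541 0.0905 3.8732
shape gamma = 1.0761, loglik = -4477.469, converged (5 iterations)
Wald test (exposure): HR = 0.8744, 95% CI 0.7560-1.0114, z = -1.81, p = 0.07065
```

Reading the output: the design expects ~1005 deaths among 5000 subjects
and has ~86% power to detect the HR of 0.8 at the 5% level. The single
seeded study then illustrates a type-II error: the estimated adjusted HR
is 0.87 in the right direction, but p = 0.07 > 0.05, so this particular
sample fails to reject a null that is in fact false — exactly the
distinction between one study and the sampling distribution that the
replication run quantifies. (Single-sample numbers are RNG-stream
specific; only the distributional summaries are comparable across
software.)

The same machinery is available programmatically:

```r
sc  <- activity_mortality_scenario()
expected_events(sc)                                   # 1005.13
rr  <- run_replications(sc, 2000, "alternative", 42)  # power estimate
cal <- calibrate_sample_size(sc, 0.80, c(3000, 4000, 5000), 1000, 42)
ens <- survival_curve_ensemble(sc, 900, c(x = 1, z = 0), master_seed = 42)
```

Other CLI commands: `generate` (cohort CSV), `fit` (fit report from a
cohort CSV), `power` (replication CSV + summary), `calibrate`
(sample-size table), `curves` (survival-curve ensemble). Scenarios are
flat `key: value` config files; see
`inst/extdata/activity_mortality.cfg`.

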