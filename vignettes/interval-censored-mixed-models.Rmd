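---
title: "Interval-censored mixed models for vial-based life-history assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-censored mixed models for vial-based life-history assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

In fly selection experiments, time-to-event traits — starvation survival,
chill-coma recovery, egg-to-adult developmental time — are not observed as
individual event times. Flies sit in vials of roughly 15–22 individuals, and
at each inspection the experimenter counts how many died (or eclosed) since
the previous inspection. Inspections are irregular: checks every few hours
during the day, one long gap overnight, and the assay ends at a fixed time
with the survivors right-censored. Every observation is therefore interval
censored, the intervals differ between day and night and between sexes
(female starvation assays run longer than male ones so both sexes reach
comparable mortality), and the experimental units are nested: individuals
within vials within replicate selection lines within selection regimes.

Standard survival tooling handles either interval censoring or crossed
normal random effects comfortably, but not both together with grouped count
data. `icmix` implements the joint model directly.

## The model

For individual $k$ in vial $v$ of replicate line $\ell$, the latent event
time (hours) is

$$ T_{k} = \mathbf{x}_v^\top \boldsymbol\beta
  + \beta_{\mathrm{age}}\,(a_v - \bar a)
  + u_\ell + u_v + \varepsilon_k, \qquad
  u_\ell \sim N(0, \sigma_{\mathrm{line}}^2),\;
  u_v \sim N(0, \sigma_{\mathrm{vial}}^2),\;
  \varepsilon_k \sim N(0, \sigma^2). $$

$\mathbf{x}_v$ dummy-codes the treatment factors — sex, selection regime
(R: cold shock reliably precedes starvation; U: uncorrelated; C: benign
control), cold-shock cue, starvation — against declared reference levels, so
the intercept is the mean for the reference cell (e.g. regime-R females
without cold shock) and every other coefficient is a contrast in hours.
$a_v$ is adult age at the start of the assay, centered at its sample mean so
the intercept keeps its reference-cell meaning.

What is observed per vial is the count $d_{vi}$ of events in each inspection
interval $(t_{i-1}, t_i]$ and a right-censored count at the final
inspection $t_m$. The likelihood is exact, with no imputation of event
times:

$$ \log L = \sum_v \Big[ \sum_i d_{vi}
  \log\!\big( \Phi(\tfrac{t_i - \mu_v}{\sigma}) -
              \Phi(\tfrac{t_{i-1} - \mu_v}{\sigma}) \big)
  + c_v \log\!\big( 1 - \Phi(\tfrac{t_m - \mu_v}{\sigma}) \big) \Big], $$

with $\mu_v = \mathbf{x}_v^\top\boldsymbol\beta + u_\ell + u_v$. Two
conventions matter and are fixed throughout:

* intervals are half-open $(lo, hi]$ — a death discovered at an inspection
  happened before it;
* the first interval is open on the left, $(-\infty, t_1]$: an event found
  at the first inspection is only known to precede it, and the normal latent
  scale admits (astronomically improbable, but nonzero-mass) negative times.
  This makes the fitted likelihood exactly the distribution the generator
  samples from. The alternative — truncating at zero — changes nothing
  numerically for the assays modeled here (the mean sits 5+ SDs above zero)
  but would make the likelihood improper against its own simulator.

A log-normal latent scale is available as a sensitivity switch
(`model_spec(..., family = "lognormal")` models log-hours with the same
machinery); the default is normal on the hours scale, which matches the
additive, symmetric way effect tables for these assays are reported.

## Priors and sampling

Priors are weakly informative and data-scaled: each coefficient gets
$N(0, 10\,s)$ and each SD a half-normal with scale $s$, where $s$ is a crude
response SD computed from event-interval midpoints (censored individuals
contribute their last boundary). At assay scale ($\sim$8000 individuals) the
likelihood dominates these priors by orders of magnitude; both scales are
overridable via `model_spec(priors = ...)`.

`fit_mcmc()` is a Hamiltonian Monte Carlo sampler written for this posterior:

* group effects are non-centered ($u = \sigma z$, $z \sim N(0,1)$) and SDs
  sampled on the log scale, which keeps the line-level funnel tractable;
* the log posterior and its analytic gradient are compiled (C++), with the
  interval mass evaluated through `erfc` in the numerically safe tail and a
  log-scale fallback once probabilities underflow ($\sim 10^{-280}$);
* a diagonal mass matrix is estimated in a warmup window and the step size
  tuned by dual averaging to an acceptance target of 0.9; trajectories use a
  jittered number of leapfrog steps (up to 96 by default). The long
  trajectories matter: the intercept and regime contrasts are correlated
  with the 450-odd group effects, and short-trajectory samplers mix poorly
  on exactly those coefficients, which are the scientific point.

Defaults are 4 chains of 1000 warmup + 1000 retained iterations. The test
suite and recovery studies run 2 chains of 400 + 400, which this sampler's
effective sample sizes (several hundred per reported parameter at assay
scale) make sufficient for the quantities checked there; those are desk-scale
choices, not recommendations for final analyses. Convergence is gated on
split-chain $\widehat R < 1.05$ and ESS > 100 for every reported parameter;
violations and divergent trajectories are attached to the result and warned
about, never silently dropped. A handful of divergences per run (well under
1% of transitions) traces to trajectories probing regions where an interval's
probability underflows, and shows no measurable effect on the recovery
studies; runs with more than a few such transitions deserve a re-run with a
higher `target_accept`.

## Validating the sampler

Two independent routes check the inference end to end:

1. **Quadrature oracle.** `grid_posterior_oracle()` integrates the exact
   posterior of any $\le 2$ free parameters on a bounded grid (everything
   else fixed) through the pure-R likelihood, sharing no code with the
   compiled sampler path. The test suite requires MCMC posterior means to
   match quadrature within 3 Monte Carlo standard errors on a suite of toys,
   including heavy-censoring and early-death shapes.
2. **Parameter recovery.** `recovery_study()` simulates experiments from
   known values, refits, and aggregates coverage, bias and RMSE. At the
   scale of the original starvation assay (432 vials, 17–22 flies each), 20
   replicates give 95%-interval coverage of every generating coefficient in
   at least 15/20 replicates and absolute biases well under 2.5 h.

An external cross-check used during development: on a simulated
developmental-time dataset, fixed-effect estimates agree with
`survival::survreg`'s interval-censored Gaussian fit (which can represent
the fixed-effect part, though not the nested random effects) to well within
a posterior SD.

## What the generator emulates — and what it does not

`simulate_survival_experiment()` reproduces the data-generating structure
the model assumes: 3 regimes × 6 replicate lines, vials nested in lines and
treatment cells, uniform 17–22 flies per vial, sex-specific assay ends
(96 h female / 72 h male by default) with 4-h daytime checks and a 12-h
overnight gap, a uniform adult-age window, and exact binning of latent
normal times with right censoring. Defaults for the fixed effects are the
published point estimates for the starvation assay, so simulated effect
tables sit in the realistic range, and assay ends were chosen so baseline
mortality lands near 50% — the calibration the original assay aimed for.

Variance components have no published values. The defaults
($\sigma = 20$ h, $\sigma_{\mathrm{line}} = 3$ h,
$\sigma_{\mathrm{vial}} = 5$ h) were chosen once so that roughly-50%
mortality is plausible and both random effects are detectable at assay
scale; they are generator settings feeding the recovery tests, not claims
about the original experiment. Likewise the inspection spacing is a
configurable guess: the real schedule is not printed anywhere.

The generator deliberately does *not* emulate: the multigenerational
selection response itself (only phenotypes under the fitted model), any
non-normal residual structure (bimodality, heavy tails), mortality during
handling, or vial-to-vial variation in inspection times (all vials of a sex
share one schedule; the model does not require this, only the generator
simplifies). Passing recovery tests therefore demonstrates that the
estimator inverts its own assumed data-generating process at realistic size
and censoring — not that real fly data satisfy those assumptions.

## Companion estimators

* **Fecundity** (`fit_negbin_glmm`): per-female egg counts, negative
  binomial with log link and line random intercept, mean–shape
  parameterization ($\mathrm{Var} = \mu + \mu^2/\theta$). Reference cell is
  regime C without cold shock or starvation, so the intercept is log
  expected eggs of control females. The early block pools 4- and 7-day-old
  females into one model with age class recorded but not a term, mirroring
  how the early-fecundity results are reported as a single block; fitted by
  maximum likelihood (glmmTMB), flagged as such in the summary.
* **Egg-to-adult survival** (`fit_binomial_glmm`): vial-level binomial with
  logit link and line random intercept (lme4). A vial random intercept is
  optional: with one binomial observation per vial it acts as an
  overdispersion term rather than a grouping level, so the default keeps
  line only. Zero-trial vials are excluded with a note; separation is
  flagged, not masked.
* **Physiology traits** (`fit_gaussian_lmm`): one measurement per line and
  sex; the line random intercept links a line's two sex measurements and the
  residual absorbs the line-by-sex remainder. Fits with fewer than two lines
  per regime are refused outright.

## Numerical choices and edge cases

* `interval_log_prob` evaluates $\log[\Phi(b)-\Phi(a)]$ in whichever tail is
  safe (upper-tail complements when both bounds are positive, symmetric in
  the lower tail, log-difference-of-log-CDFs once probabilities underflow);
  it is exact against an error-function oracle to $10^{-10}$ and partition
  sums are 1 to $10^{-10}$.
* Zero-length or non-chaining intervals, count mismatches, misplaced
  censored counts, unknown factor labels and duplicated vial ids are
  validation errors with the vial named — never silently repaired.
* Ties between a latent time and a boundary (probability zero under the
  continuous model, possible in floating point) bin left, matching the
  half-open convention.
* Factors that do not apply to a trait (sex for pooled developmental time)
  carry the explicit label `not_applicable`; fitting a spec that references
  such a factor is an error rather than a silent drop.

## Reporting conventions

Published effect tables for these assays list only statistically supported
effects. `icmix` treats that as a *reporting filter*, not model selection:
the full fixed-effect structure stays in the fit, and
`render_effect_table(..., significant_only = TRUE)` reproduces the
filtered view. The recovery studies fit the same term structure the
generator uses (regime, sex/starvation, cue, and the regime × treatment
interaction, plus the centered age covariate for starvation survival).

## Known limitations

* The latent-normal likelihood treats the response scale as exactly normal;
  strongly skewed traits should use the log-normal switch and judge fit
  sensitivity.
* Wald intervals in the ML-based companion models (glmmTMB / lme4) are
  asymptotic; at 18 lines they are serviceable but not exact, which is one
  reason the time-to-event models — the scientific core — are fully
  Bayesian instead.
* The sampler's static trajectories (jittered-length HMC rather than a
  dynamic no-U-turn scheme) trade some adaptivity for simplicity; the grid
  oracle and recovery suites are the guardrails that justify the trade.
* `grid_posterior_oracle` is quadratic in grid points and capped at two free
  parameters by design; it is a verification tool, not an estimator.
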