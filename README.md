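# icmix — interval-censored mixed models for vial-based life-history assays

`icmix` analyzes the trait data produced by fly selection experiments in
which *Drosophila melanogaster* populations evolved under fluctuating
stress: three selection regimes (R — a cold-shock cue reliably precedes
starvation; U — cue and starvation uncorrelated; C — benign control), six
replicate lines per regime, and assays of starvation survival, chill-coma
recovery, developmental time, fecundity, egg-to-adult survival and
physiology.

The package's core is a Bayesian hierarchical model for **interval-censored
time-to-event counts**. Flies are assayed in vials; at each inspection only
the number of deaths (or eclosions) since the previous inspection is
recorded, inspection gaps vary (longer overnight), and survivors at the
assay end are right-censored. The latent event time of fly *k* in vial *v*
of replicate line *ℓ* is modeled as

    T_k = x_v' β + β_age (a_v − ā) + u_ℓ + u_v + ε_k,
    u_ℓ ~ N(0, σ_line²),  u_v ~ N(0, σ_vial²),  ε_k ~ N(0, σ²)

with treatment-coded fixed effects (sex, selection regime, cold-shock cue,
starvation, and their interactions) in hours, and the exact
interval-censored likelihood — each count contributes
`log[Φ((t_i − μ_v)/σ) − Φ((t_{i−1} − μ_v)/σ)]`, censored counts the upper
tail. Inference is Hamiltonian Monte Carlo (compiled gradient, non-centered
group effects, adapted diagonal mass matrix), validated against a
deterministic quadrature oracle and parameter-recovery studies at the scale
of the original assays (~435 vials, ~19 flies per vial).

Around the core sit the rest of the analysis pipeline:

* `fit_negbin_glmm()` — overdispersed per-female egg counts (log-link
  negative binomial, line random intercept);
* `fit_binomial_glmm()` — per-vial egg-to-adult survival (logit link);
* `fit_gaussian_lmm()` — one-measurement-per-line physiology traits;
* `simulate_survival_experiment()`, `simulate_fecundity()`,
  `simulate_eclosion()`, `simulate_line_traits()` — synthetic experiments
  with the full nested design, for testing every stage without any data
  download;
* `run_pipeline()` / `recovery_study()` — config-driven
  simulate → fit → report runs with manifests, effect tables
  (`render_effect_table()`) and figures (`plot_survival_summaries()`).
  A thin CLI wrapper lives at `inst/cli/icmix.R`.

## Worked example

Simulate a starvation assay at the published scale — the generating fixed
effects are the published point estimates (intercept 104.64 h for regime-R
females without cold shock, SexM −25.80, SelU −3.89, SelC −17.92,
CueCs −7.56, SelC:CueCs 3.58) — then refit and print the effect table:

```r
library(icmix)

sim <- simulate_survival_experiment(paperlike_default_params(seed = 3))
spec <- model_spec("starvation survival",
                   fixed = c("Sex", "Sel", "Cue", "Sel:Cue"),
                   age_covariate = TRUE)
fit <- fit_mcmc(sim$records, spec, chains = 2, warmup = 500, iter = 500,
                seed = 11)
s <- summarize(fit)
render_effect_table(s[s$term %in% c(fit$term_names, "sigma_resid",
                                    "sigma_line", "sigma_vial"), ])
```

```
Effect               Estimate               95% C.I.
Intercept              100.93        (98.22, 103.57)
SexM                   -25.62       (-26.97, -24.29)
SelU                    -1.75          (-5.13, 1.88)
SelC                   -14.76       (-18.25, -11.10)
CueCs                   -7.24         (-9.71, -5.06)
age_c                   -0.05          (-0.15, 0.04)
SelU:CueCs              -0.34          (-3.70, 2.98)
SelC:CueCs               3.06          (-0.14, 6.32)
sigma_resid             19.99         (19.57, 20.45)
sigma_line               2.35           (1.22, 3.89)
sigma_vial               5.08           (4.39, 5.74)
```

Each row is a contrast in hours of starvation survival against the
reference cell; the posterior means land near the generating values
(differences of a couple of hours reflect the particular line and vial draws
of this replicate — with six lines per regime, regime contrasts carry that
uncertainty honestly in their wider intervals), the intervals separate males
(−26 h), the control regime (−15 h) and the cold-shock cost (−7 h) cleanly,
and the variance components recover the generator's 20 / 3 / 5 h. `recovery_study()` repeats this
simulate-and-refit loop and reports coverage, bias and RMSE per coefficient.

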