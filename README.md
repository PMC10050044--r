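# nstask

Simulation and hierarchical Bayesian modelling of the **Number Switching
Task (NST)**, a cognitive effort-discounting paradigm for computational
psychiatry and individual-differences research.

## The problem

Measuring cognitive effort is usually confounded with task difficulty:
more demanding conditions are also harder to complete, so avoidance of
them mixes *effort* discounting with *probability-of-success* discounting.
The NST breaks this confound. Participants accept or reject offers of
3/6/9/12 points to categorise each digit of a nine-digit sequence as odd
or even; effort is manipulated purely by the number of odd/even *parity
switches* in the sequence (four levels: 20% → 1–2 switches, 40% → 3–4,
60% → 5–6, 80% → 7–8), while the information content of every trial is
identical. Difficulty is additionally standardised *per participant*: the
allowed completion time is calibrated as the median time on the hardest
(8-switch) familiarisation trials plus 500 ms, so success rates stay near
0.9 for everyone and choices isolate effort sensitivity.

`nstask` provides, for this design:

* **Task engine** — switch-constrained sequence generation (uniform over
  all valid parity patterns), phase schedules (practice, 32-trial
  familiarisation, 10 example offers, 80-trial main phase with five trials
  per reward-by-effort cell), the 50%-correct familiarisation pass rule,
  the time-limit calibration rule and the trial scoring rule.
* **Synthetic cohorts** — simulated participants whose accept/reject
  choices follow the hierarchical logistic choice model

  p(accept) = logit⁻¹(α_s + β^R_s·z_R + β^R²_s·z_R² + β^E_s·z_E)

  with subject-varying parameters drawn from Normal population
  distributions, plus a mechanistic performance block (completion times
  and errors) — all with known ground truth for recovery studies.
* **Model suite** — the twelve fixed/varying logistic variants
  (`model_catalogue()`), fitted by MCMC (JAGS with the `glm` module),
  with rank-normalised split-R̂ / bulk-ESS diagnostics.
* **Comparison** — WAIC on the deviance scale with standard errors of
  model differences from paired pointwise contributions, posterior (and
  prior) predictive acceptance curves per design cell, and Pearson
  confound-check correlations (effort sensitivity vs success rate;
  acceptance vs completion time).
* **Pipeline** — `run_recovery()` chains simulate → fit → compare →
  recover → report, with CSV/JSON artifacts, a YAML config, and a thin
  CLI (`inst/cli/nst-cli.R`).

## Worked example

```r
library(nstask)

study <- simulate_study(nst_hyperparameters(), n_subjects = 20, seed = 1)
print(study)

cfg <- nst_config(seed = 1, n_subjects = 20, models = c(1, 9),
                  control = sampler_control(chains = 4, adapt = 300,
                                            warmup = 300, iter = 750),
                  verbose = FALSE)
report <- run_recovery(cfg)
print(report)
```

```
NST synthetic study: 20 subject(s), 1600 trials, 0 excluded
  mean acceptance 0.777; mean success (accepted) 0.931
NST parameter-recovery report
  seed 1, 20 subjects, 1600 trials
  mean acceptance 0.777, mean success rate 0.933 (SD 0.065)
  best model by WAIC: 9
  model comparison:
 model_id    waic  se_waic delta_waic se_delta rank
        9 1337.05 46.51504     0.0000  0.00000    1
        1 1700.48 41.50313   363.4307 36.61912    2
  population-mean recovery (best model):
      term truth posterior_mean posterior_sd    lower89    upper89   abs_bias
 intercept  2.20      2.0203553    0.2344896  1.6428834  2.3992226 0.17964471
    reward  0.70      0.7374318    0.1210663  0.5459352  0.9289418 0.03743179
   reward2 -0.15     -0.3257091    0.1072375 -0.4956006 -0.1546587 0.17570910
    effort -0.70     -0.7559574    0.1391652 -0.9771314 -0.5319784 0.05595743
  subject-level truth-estimate correlations:
      term correlation  n
 intercept   0.9383710 20
    reward   0.6819106 20
   reward2   0.3141988 20
    effort   0.8730617 20
  effort_vs_success: r(18) = 0.012, p = 0.96
  acceptance_vs_time: r(78) = -0.090, p = 0.428
  intercept_vs_allowed_time: r(18) = -0.051, p = 0.832
```

Reading the output: the simulated cohort lands on the task's calibration
targets (success ≈ 0.93 with small spread at this cohort size, acceptance
well above one half). The heterogeneous generating model (9) beats the
pooled-intercept model (1) by ~363 deviance units of WAIC (≈ 10 SEs of
the difference). The population means are recovered within about one
posterior SD at n = 20 (tighter at n = 100, the package's validation
size), the subject-level effort sensitivities correlate 0.87 with their
ground truth, and the confound checks are null — as they must be, since
the simulator generates performance independently of choice parameters.
Larger cohorts sharpen all of these; the weakly-identified quadratic
reward term is the last to pin down.

The methods vignette (`vignettes/nstask-methods.Rmd`) documents the model,
priors, sampler parameterisation, generator defaults and their rationale,
and known limitations.

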