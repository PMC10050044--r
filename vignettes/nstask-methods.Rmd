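---
title: "Models and methods behind nstask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nstask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and what it measures

The Number Switching Task (NST) is a cognitive effort-discounting paradigm.
On each trial a participant is offered a reward (3, 6, 9 or 12 points — one
penny per three points) to categorise each digit of a nine-digit sequence as
odd or even. Effort is manipulated by the number of *parity switches* —
adjacent digits whose odd/even status differs. Because every sequence is a
permutation of the same nine digits, the information-processing content of a
trial is identical at every effort level; only the switch structure changes.
Four nominal demand levels (20%, 40%, 60%, 80%) map onto switch-count pairs
{1,2}, {3,4}, {5,6}, {7,8}, with the precise count drawn at random within
the pair so sequences stay unpredictable.

Difficulty is standardised *per participant*: after a 32-trial
familiarisation phase (four trials at each switch count, no time limit), the
allowed completion time for the main phase is calibrated as the median time
to complete the hardest, 8-switch familiarisation trials plus 500 ms.
Participants pass familiarisation only if at least half of their 8-switch
trials are correct (at most one wrong response), with one retry before
exclusion. In the 80-trial main phase (five trials at each of the 16
reward-by-effort combinations, randomised) a trial succeeds when at most one
digit is mis-categorised and the sequence finishes within the calibrated
limit. This construction holds success rates approximately constant across
effort levels and participants, so avoidance of high-effort offers reflects
effort discounting rather than probability discounting.

## The choice model

Accept/reject choices are modelled as Bernoulli draws with

$$
p = \mathrm{logit}^{-1}\left(\alpha_s + \beta^{R}_s\, z_R +
\beta^{R^2}_s\, z_R^2 + \beta^{E}_s\, z_E\right),
$$

where $z_R$ and $z_E$ are the standardised reward and effort levels and $s$
indexes subjects. The package fits twelve variants of this regression that
differ in which terms (intercept, reward, reward², effort, effort²) are
present and whether each is *fixed* (one shared value) or *varying* (one
value per subject under a hierarchical Normal prior); `model_catalogue()`
lists them. Model 9 (varying intercept, reward, reward², effort) is the
generating model of the synthetic cohort.

### Standardisation

Predictors are standardised against the four *design-level* values, using
the population SD of the level grid: for reward,
$z = (x - 7.5)/\sqrt{45/4}$, so the levels map to ±1.342 and ±0.447. The
effort grid (20, 40, 60, 80) is an affine image of the same 1–4 ladder and
yields identical z-values. Standardising on the design grid rather than the
realised trial mix makes z-values dataset-independent; under the balanced
main-phase schedule the distinction is negligible anyway. Quadratic terms
are plain squares of the linear z (not orthogonal polynomials); with a
symmetric four-point grid the square is orthogonal to the linear term up to
a constant shift absorbed by the intercept, so this choice mainly affects
the interpretation of the intercept, not the fit.

### Priors

Population means of varying terms get Normal(0, 1.5) priors for the
intercept and Normal(0, 1) for slopes (log-odds per standardised unit);
population SDs get Half-Normal(1); fixed terms reuse the mean priors. On
the logistic scale these are weakly-informative: prior population curves
from `prior_predictive_acceptance()` span essentially the whole (0, 1)
acceptance range without concentrating mass at the boundaries. All scales
are overridable through `nst_priors()`, and the prior-predictive utility
supports re-tuning them for other populations.

## Sampling and diagnostics

`sample_posterior()` fits the models by MCMC with JAGS, with the `glm`
module loaded so that logistic-regression blocks are updated by
auxiliary-variable samplers rather than one-dimensional slice moves. The
default budget follows the four-chains-of-1,000-retained-iterations
convention, with adaptation and warmup ahead of the retained draws; every
setting is configurable via `sampler_control()`.

Two numerical choices matter here:

* **Parameterisation.** Varying terms use a *mixed* parameterisation:
  centred (subject effects drawn around the population mean) for the
  intercept and the linear reward/effort terms, whose subject-level effects
  are strongly informed by 80 trials each, and non-centred
  ($\beta_s = \mu + \sigma z_s$, $z_s \sim N(0,1)$) for the quadratic
  terms, whose small population SDs are weakly identified and produce a
  funnel under the centred form. In benchmarks the fully non-centred model
  mixed comparably but ran several times slower, because every
  hyperparameter update then touches the whole likelihood; the mixed
  default gets the better geometry only where it is needed. The set of
  non-centred terms is a `sampler_control()` option.

* **Diagnostics.** `compute_diagnostics()` implements rank-normalised
  split-$\hat R$ and bulk effective sample size (autocorrelation summed
  under Geyer's initial positive monotone sequence), and applies the pass
  rule $\hat R < 1.01$ and ESS $> 400$ for **every** monitored parameter.
  Chains with zero variance yield `NA` and fail. The Gibbs-type backend
  produces no divergences or energy statistics, so the divergence count is
  reported as zero by construction. The slowest-mixing quantity is
  consistently the population SD of the quadratic reward term — weakly
  identified because its true value is small — and the full-size recovery
  runs therefore use a longer, thinned schedule (2,500 retained per chain
  from 7,500 post-warmup iterations) so that even that parameter clears
  the ESS and $\hat R$ bars.

## Model comparison

`waic()` computes the Widely-Applicable Information Criterion on the
deviance scale, $-2(\mathrm{lppd} - p_{\mathrm{WAIC}})$, from the draws ×
trials log-likelihood matrix, with an overflow-safe log-sum-exp for the
lppd and the posterior variance of the pointwise log-likelihood as the
penalty. The pointwise unit is the trial, the usual partition for
Bernoulli observations. `compare_models()` ranks models and reports the
standard error of each model's WAIC difference to the best model from the
*paired* pointwise contributions, which is what makes differences between
similar models far better resolved than the individual WAIC SEs suggest.
An elpd-scale accessor is included. PSIS-LOO and stacking weights are out
of scope.

## The synthetic cohort

`simulate_study()` produces tidy datasets with known ground truth. Choice
parameters are drawn independently per subject from Normal population
distributions (no correlation matrix between effects — modelling those is
left as future work, matching the model suite, which also assumes
independent effects). Performance is generated by a simple mechanistic
stand-in — the field has no agreed generative model of completion times, so
this block should not be read as an empirical claim:

* completion time = (9 × base + cost × switches − speeding × reward) ×
  lognormal noise, floored and rounded to integer milliseconds;
* errors ~ Binomial(9, per-digit error probability);
* a practice speed-up multiplier (default 0.9) applies to main-phase times
  relative to familiarisation, representing practice gains between phases.

Defaults (`nst_hyperparameters()`): intercept 2.2 (SD 0.7), reward 0.7
(SD 0.4), reward² −0.15 (SD 0.15), effort −0.7 (SD 0.45) on the
standardised log-odds scale; base 850 ms/digit (between-subject SD 170),
100 ms/switch, 10 ms/point speeding, lognormal sdlog 0.15, error
probability 0.012. These were chosen by closed-form reasoning to land on
the task's calibration targets: simulated cohorts show per-subject success
rates near 0.90 with small spread, allowed times around 9,000 ms,
completion times at roughly 0.78–0.85 of the allowed limit, acceptance
above 50% in every cell, and discounting curves that flatten with reward.

What the simulator does **not** emulate: the non-monotone dip in completion
times at the highest effort level seen in human data (where fully
alternating sequences are easier than their switch count suggests) — times
here are linear in switch count; learning or fatigue across the session;
lapses and attention failures; and any dependence between choice
parameters and performance. That last omission is deliberate and useful:
because the performance block never reads the choice parameters, effort
sensitivity and success probability are independent by construction, which
turns the confound-check correlation into a null calibration experiment.
Consequently, passing tests demonstrate the *pipeline's* correctness and
calibration, not the behavioural adequacy of the performance model.

Seeding uses a master seed with per-subject substreams, so subject *i*'s
data are identical in cohorts of any size — convenient for debugging and
for growing cohorts incrementally.

## Recovery studies and their problem sizes

`run_recovery()` chains the whole analysis: simulate → fit the requested
models → WAIC ranking → subject-level estimates from the best model →
recovery metrics → confound checks (effort sensitivity vs success rate;
per-subject-by-level acceptance vs mean completion time over completed
trials, successful or not, with a successful-only variant; overall
tendency to accept vs allowed time). The package's own validation uses:

* a 100-subject × 80-trial cohort for the headline recovery of model 9
  (population means recovered within 3 posterior SDs and 0.15 absolute
  bias; subject-level effort-sensitivity correlation ≥ 0.7, diagnostics
  passing);
* five 25-subject cohorts for the model-selection sanity check (the pooled
  intercept model must never outrank the generating model by WAIC — the
  gap is hundreds of deviance units, so the reduced size is decisive);
* 1,000 resampled 100-subject null cohorts for the type-I calibration of
  the confound check (rejection rate 5% ± 1.5% at α = 0.05).

Degenerate inputs are handled explicitly: a non-positive population SD is
a rejected state (−∞ log posterior), not an error; zero-variance chains
fail diagnostics rather than crash; rejected offers carry no performance
fields and the dataset readers enforce that invariant; and ties in WAIC
are broken by the lower model id for reproducibility.

## Known limitations

* The performance block is a stand-in; inferences about completion-time
  mechanisms should not be drawn from it.
* Subject effects are independent in both generator and models; correlated
  effects (e.g., bold subjects also being reward-sensitive) are neither
  simulated nor fitted.
* JAGS provides no HMC-style divergence diagnostics; convergence assurance
  rests on split-$\hat R$, ESS and the parameter-recovery results.
* WAIC is the only comparison criterion; with 80 trials per subject it is
  effectively leave-one-trial-out, not leave-one-subject-out, and model
  choice generalises to new trials of the same subjects rather than new
  populations.
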