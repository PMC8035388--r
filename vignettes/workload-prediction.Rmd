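---
title: "Predicting short-timescale cognitive workload from task events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting short-timescale cognitive workload from task events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(workloadcv)
```

## The problem

An operator supervising several semi-autonomous vehicles experiences a
cognitive workload that fluctuates on a timescale of seconds: a cluster of
near-critical fuel states demands attention now, a quiet stretch does not.
The detection response task (DRT; ISO 17488) measures such fluctuations
behaviourally: a vibrotactile stimulus arrives every 3–5 s and the
operator responds with a pedal press; slower reaction times (RTs) and more
omitted responses index higher momentary workload.

`workloadcv` implements the full analysis chain for asking whether
observable events in the primary task *predict* DRT performance a few
seconds later, for participants the model has never seen:

1. a headless simulator of the multi-UAV refuelling task plus a generative
   DRT workload model (`simulate_study()`),
2. trial construction and the study's exclusion filters (`build_trials()`,
   `exclude_participants()`, `exclude_trials()`),
3. per-trial predictor construction (`build_feature_table()`),
4. mixed-effects model families (`fit_lmm()`, `fit_glmm()`, `fit_tpm()`,
   `fit_zip()`),
5. between-subject cross-validated subset selection (`make_folds()`,
   `enumerate_specs()`, `run_cv()`, `normalize_msd()`,
   `rank_and_stability()`),
6. descriptive reports (`ladder_report()`, `effect_report()`,
   `exponent_sweep()`, `overload_comparison()`).

## The task and its simulator

Three, five or seven UAVs move at 75 px/s on a 1920×1080 screen,
reflecting at the boundaries. Fuel drains at 5% of a tank per second.
Hovering over a UAV (≥ 0.3 s) reveals its gauge; clicking refuels it.
Five scored events follow from the 25% refuel zone:

| event | meaning | points |
|-------|---------|-------:|
| HR  | click with fuel < 25% (hit refuel; gains 50–100% of tank) | +2000 |
| FAR | click with fuel ≥ 25% (premature refuel) | −500 |
| HHO | informative gauge check, fuel < 25% | +50 |
| FAHO| gauge check with fuel ≥ 25% | −50 |
| MR  | tank empty: the UAV crashes and is instantly replaced (spawn fuel 70–100%) | −1000 |

Sessions are 21 two-minute blocks; every consecutive triple of blocks is a
permutation of the 3/5/7-UAV difficulties (`draw_block_schedule()`). The
DRT prompt schedule draws inter-stimulus intervals from Uniform(3, 5) s
(mean ≈ 4 s); a response later than the 2.5 s window, or no response,
counts as an omission.

The simulated operator is a *noisy-memory* agent, not a model of any
specific human: it keeps drifting internal estimates of every UAV's fuel
(drift SD `memory_noise · load_scaling^(K−3) · √Δt`, reset to truth on
each check), acts at `check_rate` actions/s on the lowest-estimate UAV,
refuels directly when a recent check showed low fuel (`verify_horizon`)
and re-checks otherwise, and occasionally lapses. The analysis pipeline
never depends on these internals — any event/DRT log with the documented
schema is accepted. Internally the simulator is event-driven on a fixed
0.1 s tick: action times are geometric inter-tick gaps (equivalent to a
per-tick Bernoulli process), fuel trajectories are piecewise linear and
crash times are solved analytically, so replicate studies are cheap.
`step_dynamics()` exposes the literal tick physics.

DRT outcomes come from a two-part generative model
(`workload_model()`): a logistic sub-model for omissions and a truncated
log-normal sub-model for RT given response, both driven by difficulty
dummies (+2, +4 UAVs vs 3), block number, the weighted fuel level, the HHO
and FAR counts in the preceding 3 s, and (omissions only) the
previous-trial omission. Default magnitudes mimic effects of roughly
±40–75 ms on a ~450 ms baseline — e.g. `beta_weightfuel = −0.08` log-ms
per scaled unit, `beta_hho3s = 0.08` per event — with a participant
random intercept (SD 0.15) and residual SD 0.30 on log-RT.

### What the generator emulates — and what it does not

The generator reproduces the *structure* that matters for testing the
pipeline: the event taxonomy and payoffs, realistic event rates that rise
with difficulty, the prompt cadence, known ground-truth effects, and
per-participant RNG streams (adding participants never perturbs earlier
ones). It does not emulate learning across days, strategic shifts in
operator policy, RT sequential dependencies beyond the previous-omission
term, or motor/hardware timing noise. Passing recovery tests therefore
shows the *pipeline* is correct and sensitive at realistic signal
strengths — not that the human data satisfy the model.

## Trials, exclusions

A *trial* is the interval between consecutive DRT prompts. Exclusions
follow two rules: (a) a participant-day is removed when its omission rate
exceeds 45% (strictly) in at least two of the three difficulty
conditions — applied per day, since a participant can fail the rule on one
day only; (b) the first trial of each block (no previous-trial
information) and trials whose last operator interaction is absent or more
than 100 s old are removed. "Interaction" means any hover or click
(FAHO/FAR/HHO/HR); a crash is not an operator action. Every filter appends
to a provenance audit trail, and removed + retained counts always equal
the input count.

## Predictors

For each trial the feature table contains:

* occurrence flags per event type for 3, 4 and 5 s windows before the
  prompt. Windows are half-open `(prompt − w, prompt]`: an event
  simultaneous with the prompt precedes the response, so it counts;
* counts `#HHO3s`, `#FAHO3s`, `#FAR3s` in the 3 s window;
* **WeightFuel**, the power mean of order *p* of the `K` on-screen fuel
  fractions `f_k`:
  `WeightFuel = (Σ_k f_k^p / K)^(1/p)`, default `p = 1/4`. For `p < 1`
  low fuel levels dominate, so the statistic falls sharply when any UAV
  nears a crash; `p = 1` is the arithmetic mean. It is non-decreasing in
  every `f_k` and non-decreasing in `p`;
* **OrdFuel**, the ascending rank (1 = lowest, minimum rank on ties) of
  the last-checked UAV's fuel among all on-screen fuels at the hover
  instant — a proxy for how well-targeted the operator's checking is;
* **MissPrevDRT**, the previous trial's omission flag;
* optional within-participant z-standardization (sample SD, `n − 1`;
  zero-variance participants get zeros with a warning). Because the
  transform uses only that participant's own data, it is identical
  whether applied before or after fold splitting — no leakage.

Fuel levels at prompt time come from the simulator's snapshot log when
present. For interaction-only logs (as a real recording system would
produce) they are reconstructed by linear drain extrapolation from each
UAV's last logged observation, dropping crashed UAVs and those whose
extrapolated tank has emptied; post-refuel levels are unobserved and
imputed at the midpoint of the possible range. The two paths share one
interface, and on simulated data the reconstruction correlates strongly
with ground truth (checked in the test suite).

## Models

All models are fit by maximum likelihood (not REML) so AIC/BIC are
comparable across fixed-effect sets; `k` counts fixed effects plus
variance components. Families:

* linear mixed model for log-RT (natural log of RT in ms), participant
  random intercept;
* binomial (per-trial Bernoulli, logit) and Poisson (log) GLMMs, Laplace
  approximation;
* two-part log-normal model: independent occurrence (omission, logistic)
  and intensity (log-RT on responded trials) sub-models, each with its own
  participant intercept. With no shared parameters the joint
  log-likelihood is exactly the sum of the parts, and with zero omissions
  the intensity fit *is* the LMM fit;
* zero-inflated Poisson for crash counts in the 5 s after a prompt
  (structural-zero logit with shared covariates; random intercept in the
  count part).

Millisecond-scale summaries of log-scale coefficients use
`Δms = exp(β₀ + δ) − exp(β₀)` at the baseline profile, and the cumulative
block effect is the coefficient × 20 increments (block 1 → 21); both are
reporting conventions, stated in the output rather than baked into fits.

## Between-subject cross-validation

Participants are partitioned into `k = 5` seeded folds of near-equal size.
Candidate specs are all `2^m` subsets of the optional predictors, each
with difficulty and block always included, plus four baselines
(difficulty + block, block, difficulty, intercept); additive fixed
effects and a participant random intercept only — interaction terms are
supported in the descriptive ladders but deliberately excluded from the
enumeration, where discrete predictors with sparse cells make interaction
estimates unstable.

Each fold in turn is the *training* set and the pooled remaining four
folds the test set — the deliberately demanding inverted 20/80 split;
`invert = FALSE` gives the conventional direction. Test-set predictions
use fixed effects only (unseen participants take the population-mean
intercept of zero). Performance is the mean squared deviation (MSD)
between observed and predicted log-RT (or omission indicator vs predicted
probability). The two-part path scores log-RT only, since its occurrence
part cannot predict new participants' omissions.

NMSD subtracts a centering constant from every (fold, spec) MSD. The
package centers on the *per-analysis grand mean*: centering per spec
would zero out exactly the between-spec differences the ranking needs,
while grand-mean centering leaves the ordering of per-spec means
untouched. A per-fold centering (removing between-fold level differences)
is available via `center = "per_fold"`. Failed cells are flagged missing
and dropped pairwise with a warning rather than aborting the analysis.

## Numerical and design choices

* Fuel strictly below 25% counts as a hit; the boundary case cannot occur
  in continuous simulation but the rule is fixed for reproducibility.
* After an omission the next prompt onset is drawn Uniform(3, 5) s from
  the previous *onset*, keeping the ~4 s cadence; the omission cutoff is
  the 2.5 s ISO-convention response window. Both are conventions the task
  description leaves open.
* The generator applies its weighted-fuel effect per fixed-scale unit
  `(WeightFuel − 0.45)/0.14`, constants chosen to match the statistic's
  realized distribution in the simulated task, because a generator cannot
  z-standardize within participant prospectively. The analysis side uses
  within-participant z-standardization; recovery tests use the stored
  generative transform.
* Free initial gauge reads are consumed at block start (estimates start at
  truth; no events logged); a UAV spawned mid-block gets one unscored
  first hover.
* lme4 fits use `calc.derivs = FALSE`; singular variance estimates are
  pinned at zero and flagged rather than raised as errors.

## Problem sizes

Replicate-study checks in the test suite use 40 participants × 2 days ×
21 blocks with one-minute blocks (~15 trials/block at the 4 s cadence) and
the reduced `m = 3` enumeration (12 specs) over WeightFuel, #HHO3s and
#FAR3s — the package's chosen balance between statistical resolution and
a test suite that runs in minutes. With these sizes, across 20 replicate
studies the mean bias of every generative coefficient stays within 10%,
the three true predictors dominate the top-ranked specs in ≥ 4/5 folds in
at least 80% of replicates, zeroing the effects makes the
difficulty + block baseline the most frequent winner, and in the exponent
sweep the `p < 1` weighted-fuel variants outrank the `p > 1` variants.
These statements are computed by the test suite itself, not quoted from
anywhere.

## Limitations

* The operator policy is a heuristic; absolute event rates are plausible
  rather than calibrated to human data.
* Two-part and LMM log-likelihoods are reported on the log-RT density
  scale; comparisons are valid within a family fit to the same rows.
* OrdFuel on interaction-only logs inherits the reconstruction's
  approximations between a hover and the prompt.
* The pipeline predicts 3–5 s ahead from logged events; it is not an
  online deployment, and within-subject cross-validation is out of scope.
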