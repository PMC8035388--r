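# workloadcv

Predicting short-timescale (3–5 s) fluctuations in an operator's cognitive
workload from events in their primary task.

## The problem

Operators supervising several semi-autonomous vehicles are probed with a
detection response task (DRT, ISO 17488): a vibrotactile stimulus every
3–5 s, answered with a pedal press. Slower reaction times and omitted
responses index momentary workload. The scientific question is whether
observable events in the primary task — here a multi-UAV refuelling game
with five scored event types (hit/false-alarm hover-overs, hit/false-alarm
refuels, crashes) — *predict* DRT performance a few seconds later, for
participants a model has never seen.

`workloadcv` provides the full chain: a headless simulator of the task
with a generative DRT workload model (ground truth known, so every stage
is testable without human data), trial construction and exclusion filters,
per-trial predictor construction, mixed-effects model families, and
between-subject cross-validated subset selection.

## The statistic and the selection procedure

The headline predictor is the **weighted fuel level**, the power
(Minkowski) mean of order *p* of the K on-screen fuel fractions
f<sub>1</sub>…f<sub>K</sub>:

    WeightFuel = ( Σ_k f_k^p / K )^(1/p),   default p = 1/4

For p < 1 low fuel levels dominate, so the statistic drops sharply when
any UAV nears a crash. Further predictors: windowed event flags/counts
(3/4/5 s before the prompt), the fuel rank of the last-checked UAV
(OrdFuel), and the previous trial's omission (MissPrevDRT).

Model selection is by between-subject cross-validation: participants are
split into 5 folds; each fold in turn *trains* a random-intercept model
(~20% of participants) and the pooled remaining folds are predicted with
fixed effects only. Candidate models are all 2^m subsets of the optional
predictors (difficulty and block always included) plus four baselines.
Performance is the mean squared deviation (MSD) between observed and
predicted log-RT (or omission probability), recentred to NMSD by
subtracting the analysis-wide grand mean; lower is better.

Model families: ML-fitted linear mixed models for log-RT, binomial and
Poisson GLMMs, a two-part log-normal model (logistic omissions + log-normal
RT intensity, independent random intercepts, exactly factorizing
likelihood), and zero-inflated Poisson for post-prompt crash counts.

## Worked example

```r
library(workloadcv)

study <- simulate_study(10, config = task_config(), seed = 1, n_days = 1)
study
#> Simulated workload study
#>   participants: 10   days: 1
#>   task events:  19799
#>   DRT prompts:  6190 (omission rate 0.183)

ds <- new_dataset(study$events, study$drt, study$snapshots)
ds <- exclude_trials(exclude_participants(ds))
ds
#> DRT dataset (in-memory)
#>   trials: 5979   events: 19799   participants: 10
#>                  step trials_removed trials_retained
#>                ingest              0            6190
#>  exclude_participants              0            6190
#>        exclude_trials            211            5979

features <- build_feature_table(ds, windows = 3, standardize = TRUE)
plan  <- make_folds(unique(features$participant_id), k = 5, seed = 1)
specs <- enumerate_specs(c("weightfuel_z", "hho3s_z", "far3s_z"))
cv    <- normalize_msd(run_cv(features, specs, plan, "logRT", "lmm"))
rs    <- rank_and_stability(cv, top_frac = 0.25)
head(rs$ranking[, c("predictors", "msd", "nmsd", "rank")], 5)
#>                                      predictors   msd      nmsd rank
#> 1 difficulty+block+weightfuel_z+hho3s_z+far3s_z 0.136 -0.006188    1
#> 2         difficulty+block+weightfuel_z+hho3s_z 0.137 -0.005302    2
#> 3         difficulty+block+weightfuel_z+far3s_z 0.139 -0.003263    3
#> 4                 difficulty+block+weightfuel_z 0.140 -0.002577    4
#> 5              difficulty+block+hho3s_z+far3s_z 0.142 -0.000573    5
```

The generative model gives the weighted fuel level, the 3-s HHO count and
the 3-s FAR count real effects on log-RT (about ∓40 ms each on a ~450 ms
baseline). The cross-validation recovers exactly that: the spec containing
all three true predictors attains the lowest mean NMSD (here 0.136 mean
squared deviation on log-RT, −0.006 after recentring), ranks first in all
five folds (`rs$best_spec_by_fold`), and dropping any true predictor
worsens out-of-sample prediction.

Descriptive layers: `ladder_report()` (AIC/BIC comparison ladders across
difficulty/day/block models), `effect_report()` (per-day coefficients with
approximate ms-scale effects), `exponent_sweep()` (CV rerun for
p ∈ {1/8, 1/4, 2, 4}), `overload_comparison()` (event-based vs refined
predictors of post-prompt crashes, zero-inflated Poisson).

A thin command-line wrapper is installed at `exec/workloadcv`
(`simulate`, `prepare`, `features`, `cv`, `report` subcommands); see the
header of that script for usage.

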