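# alarmeval

Evaluation machinery for clinical predictive alarm indices, built around
the Modified Early Warning Score (MEWS) as the worked example.

## The problem

Early-warning scores turn bedside vital signs into an integer risk
score; crossing a threshold raises an alarm. Conventional validation
(per-admission sensitivity/specificity, ROC curves) says nothing about
two properties that decide whether such a system is usable: whether
alarms arrive inside an *actionable* window before the event, and how
many alarms — true and false — a care team must absorb. `alarmeval` is
for researchers evaluating scoring systems on irregularly sampled
electronic-health-record data who need both the conventional
patient-level picture and an event-level picture built on the
prediction horizon and lead time.

## What it computes

**Scoring.** MEWS assigns 0–3 points per parameter (systolic blood
pressure, heart rate, respiratory rate, temperature, AVPU consciousness
mapped from the Glasgow Coma Score) with maximum total 14. Three score
series variants handle irregular sampling: event-driven scoring with
last-observation-carried-forward imputation (`MEWS_base`), and
interval scoring over a regular grid of length `t_mews` using the
interval median or the worst (most points) value.

**Patient-level.** Any-crossing confusion matrix at threshold *k*,
the derived panel (TPR, FPR, PPV, NPV, accuracy, F1, work-up-to-detection
ratio WDR = (TP+FP)/TP), and the ROC / precision–recall sweep over all
14 thresholds *k* = 0…13.

**Event-level.** With prediction horizon τ and lead time τ₀, alarms are
classified early / on-time / late / post-event; the package computes

- time-dependent sensitivity `S = n_predicted / n_events` (events with
  at least one on-time alarm),
- the bootstrapped false-positive ratio: the probability that a random
  τ-length window in a control recording contains an alarm, with mean
  and standard deviation over *M* windows per control, plus derived
  accuracy / predictive values / F1 per bootstrap replicate,
- WDR with bootstrap uncertainty: `1 + Σᵢ μ̂ᵢ / N_case`,
- per-patient alarm burden (alarms/hour `r`, alarm proportion `ρ`, and
  their false-alarm counterparts `r⁰`, `ρ⁰` with the horizon length
  subtracted from the case denominator),
- pooled alarm time profiles (per alarm and per event, plus missed
  events).

**Synthetic cohorts.** A generator reproduces the structural features
of an ICU cohort — log-normal stays moment-matched to published
median/IQR, per-parameter Poisson sampling at published rates,
baselines centred in the zero-point bands with between-patient
heterogeneity, and a plantable pre-event deterioration drift — so every
evaluator is testable without protected data.

## A worked example

```r
library(alarmeval)

cohort <- simulate_cohort(generator_spec(n_case = 30, n_control = 60,
                                         seed = 7))
cfg <- eval_config(k = 4, tau = 12, tau0 = 0, m = 200, seed = 11)
ev <- evaluate_cohort(cohort, cfg)
ev
#> <ews_evaluation>
#> <ews_config>
#>   threshold k       : 4 (alarm when total > k)
#>   horizon tau       : 12 h
#>   lead time tau0    : 0 h
#>   score variant     : base (event-driven)
#>   bootstrap windows : 200 (seed 11)
#>   patient-level: TPR 1.000, FPR 0.050, PPV 0.909, WDR 1.1
#>   sweep: AUROC 1.000, AUPRC 0.944
#>   event-level: S = 1.000 (26/26 events, 4 excluded)
#>   bootstrap FPR: 0.017 (std 0.129, M = 200)
#>   WDR: 1.04 (std 0.03)
```

Reading the output: every simulated deterioration was caught by an
alarm inside the 12 h horizon (`S = 1`); a random 12 h window in a
control recording contains a false alarm with probability ≈ 0.017; and
1.04 patients are worked up per detected event. Four cases were too
short for the 12 h horizon and are excluded (listed in
`exclusions(ev$sensitivity)`). `tidy(ev)` and `glance(ev)` return the
panels as tibbles; `autoplot()` draws the ROC/PRC sweep and score
traces, `plot_time_profile()` and `plot_burden_decay()` the burden
views. High synthetic discrimination is a property of the generator's
clean deterioration signal, not a clinical claim.

A command-line front end covers the same pipeline
(`inst/cli/alarmeval`): `simulate`, `score` and `evaluate` subcommands
with YAML generator specs, CSV/JSON outputs and a JSON run manifest per
invocation; see `?run_cli`.

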