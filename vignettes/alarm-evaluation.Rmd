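---
title: "Evaluating early-warning alarm indices with alarmeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating early-warning alarm indices with alarmeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmeval)
library(dplyr)
```

## The problem

Early-warning scores condense a patient's vital signs into a single
integer meant to flag physiological deterioration. Conventional
validation reports sensitivity, specificity and discrimination at the
level of whole admissions, which hides two properties that decide
whether an alerting system is usable at the bedside: **when** the alarms
arrive relative to the adverse event, and **how many** of them a care
team has to absorb. `alarmeval` implements a patient-level and an
event-level evaluation framework around the Modified Early Warning
Score (MEWS) applied to irregularly sampled electronic-health-record
vital signs, together with a synthetic cohort generator so that the
whole machinery can be exercised and tested without access to protected
clinical data.

## Scoring model

MEWS assigns 0--3 points per parameter — systolic blood pressure (SBP),
heart rate (HR), respiratory rate (RR), temperature (TEMP) and the AVPU
consciousness level — and sums them; the maximum total is
$3+3+3+2+3 = 14$. Consciousness is recorded as a Glasgow Coma Score
(GCS) and mapped one-to-one onto AVPU: Alert = GCS 14--15, Voice =
10--13, Pain = 4--9, Unresponsive = 3.

The published point table is written over integer-labelled bands, which
leaves one-unit gaps on the real line (e.g. SBP between 70 and 71). We
close each gap by treating the lower-severity band as half-open at the
shared edge, so every real value receives exactly one point assignment;
the full convention is documented in `?mews_table` and the table is a
plain tibble, so alternative scoring systems (or boundary conventions)
can be supplied wherever a `table` argument is accepted.

EHR vitals arrive irregularly and per parameter. Three score-sampling
variants are provided by `score_cohort()`:

* **base** (event-driven): a new total at every measurement time of any
  parameter, with all other parameters carried forward
  (last-observation-carried-forward, LOCF). Scoring starts at the first
  time every mandatory parameter has been observed at least once — we
  take the view that a score computed before a parameter was *ever*
  measured has no defensible value, and emit none.
* **median** over regular intervals of `t_mews` hours: the interval's
  measurements of each parameter are summarized by their *lower element
  median* (always an observed value). An interpolated median could fall
  into a band neither observed value occupies; the element median keeps
  the worst-vs-median dominance property exact and testable.
* **worst** over the same grid: the interval value attracting the most
  points, ties broken by the most recent value. "Worst" is defined
  through the points because both tails of a band structure can be
  abnormal (very low *and* very high SBP score points); the
  score-relevant reading is the only unambiguous one.

Interval grids are anchored at admission and scores are stamped at the
interval *end*, so no score uses information from its own future. An
interval without new measurements of a parameter carries the last
recorded raw value forward and flags it imputed. LOCF has no expiry by
default (slow-moving parameters such as temperature and GCS make this
defensible, though it can misrepresent fast-moving ones); a finite
`max_carry_h` is available, and a time point whose mandatory carried
value has expired yields no score. A record with no GCS at all is still
scoreable — the consciousness term is omitted and the total is capped
at 11.

## Alarms, prediction horizon, lead time

An alarm is an instantaneous notification at every score sample whose
total *strictly exceeds* a threshold $k$ (`generate_alarms()`); with a
maximum total of 14, the 14 thresholds $k = 0,\dots,13$ exhaust the
scale. No lockout or grouping is applied — alarm-protocol design is a
separate question and out of scope here.

For a case patient with event at $t_{event}$, two windows classify each
alarm (`classify_alarms()`): the **prediction horizon**
$[t_{min}, t_{max}]$ of length $\tau$ and the **lead time**
$(t_{max}, t_{event})$ of length $\tau_0$, with
$t_{max} = t_{event} - \tau_0$. Alarms are *early* before $t_{min}$
(not actionable), *on-time* inside the closed horizon, *late* inside
the lead time (too close to act), *post-event* afterwards; early, late
and post-event alarms are all false alarms, and every control-patient
alarm is false. The published definition does not state whether the
horizon is closed at its edges; we chose the closed interval — an alarm
exactly at $t_{max}$ still leaves the full lead time $\tau_0$ for an
intervention — and record that this is a package decision, not an
inference.

## Patient-level evaluation

`patient_confusion()` scores each patient once: a case whose score ever
crosses the threshold is one true positive regardless of how often it
crosses; a crossing control is one false positive. `confusion_metrics()`
derives TPR, FPR, PPV, NPV, accuracy, F1 and the work-up-to-detection
ratio $WDR = (TP+FP)/TP$ (the number of patients worked up per detected
event). Zero-denominator ratios are returned as flagged `NaN` rather
than errors so that full threshold sweeps never abort.
`threshold_sweep()` evaluates all 14 thresholds and integrates ROC and
precision-recall curves by the trapezoidal rule over the discrete
operating points plus the (0,0) and (1,1) ROC anchors — the score is a
15-level integer, so no further interpolation is honest. The AUROC
computed this way coincides (to numerical precision) with the pairwise
concordance of per-patient maximum scores, which the test suite checks
against an exhaustive oracle.

## Event-level evaluation

**Time-dependent sensitivity.** An event is predicted if at least one
alarm is on-time; $S^{\tau,\tau_0}$ is the fraction of events predicted
(`time_dependent_sensitivity()`). Cases whose stay is shorter than
$\tau + \tau_0$ cannot contain the window and are excluded (with a
machine-readable report). In the limit $\tau \to$ whole stay,
$\tau_0 = 0$, every pre-event alarm is on-time and $S$ must equal the
patient-level TPR — but only if the short-stay exclusion is not applied,
since a whole-cohort $\tau$ exceeds every shorter stay. The function
therefore takes `exclude_short_stays`; the default `TRUE` mirrors the
study design, and the equivalence tests run with `FALSE`.

**Bootstrapped false-positive ratio.** For each control, `m` windows of
length $\tau$ are placed uniformly at random over the recording
(controls shorter than $\tau$ are excluded), sorted and indexed; the
binary indicator $T_{ij}$ records whether window $j$ of control $i$
contains an alarm. The FPR estimate is the grand mean of $T_{ij}$
(`bootstrap_fpr()`). The printed spread composition subtracts the
per-window *count* of triggered controls from each binary indicator,
which mixes a count with a proportion; the package's default
(`variance = "proportion"`) uses the per-window sample standard
deviation of the indicators — the standard binomial estimator — and
composes window indices by root mean square, while
`variance = "literal"` reproduces the printed form verbatim for
comparability. Derived metrics (accuracy, predictive values, F1) use
the same scheme (`bootstrap_metrics()`): per window index a confusion
matrix combines the fixed case-side outcome with that window's control
false positives, each metric is computed per replicate, and means and
standard deviations are taken across replicates (zero-denominator
replicates are skipped and counted; a single replicate has standard
deviation 0 by convention). All window draws come from one seeded
generator, so identical configuration and seed give bit-identical
results.

**Work-up-to-detection ratio.**
$\hat\mu_{WDR} = 1 + \sum_i \hat\mu_i / N_{case}$ with
$\hat\sigma_{WDR} = \sqrt{\sum_i \hat\sigma_i^2} / N_{case}$, where
$\hat\mu_i, \hat\sigma_i$ are the per-control moments of the trigger
indicators and $N_{case}$ the number of predicted events (`wdr()`).

**Burden.** Per patient, `alarm_burden()` reports the alarm rate
$r = N_{alarms}/T_{recording}$, the alarm proportion
$\rho = N_{alarms}/N_{scores}$, and their false-alarm counterparts
$r^0, \rho^0$. For a case the $r^0$ denominator is
$T_{recording} - \tau$, because no false alarm can occur inside the
horizon by definition; a case recording not exceeding $\tau$ has no
valid denominator and is flagged. Case patients excluded from the
sensitivity at large $\tau_0$ are *kept* in the burden metrics — only
the $\tau$-length constraint applies there.

**Time profiles.** `time_profiles()` pools case alarms over the early /
on-time / late classes, counts missed events (cases with no on-time
alarm), and normalizes per alarm (the three alarm classes sum to one)
and per event.

## The synthetic cohort generator

`generator_spec()` + `simulate_cohort()` emulate the structure of the
kind of ICU cohort this framework targets:

* **Stay lengths** are log-normal, moment-matched to a median of 86.3 h
  (IQR 245.9 h) for cases and 160.9 h (IQR 193.2 h) for controls. The
  log-normal is a convention, not an inference — it is strictly
  positive, right-skewed, and its two parameters are pinned by the two
  published statistics (`lognormal_from_median_iqr()`).
* **Measurement times** follow independent per-parameter Poisson
  processes at the published group mean rates (cases: GCS 0.3, TEMP 1,
  SBP 1.2, RR 2, HR 2.2 per hour; controls: 0.1, 0.4, 0.5, 0.7, 0.8).
  Scheduled nursing rounds would cluster measurements; the Poisson
  process is the simplest mechanism reproducing the mean rates.
* **Baseline physiology** is stationary and centred in the zero-point
  bands (SBP 120, HR 75, RR 12, TEMP 36.8, GCS 15), with within-patient
  fluctuation plus a persistent per-patient offset
  (`between_sd`) — ICU patients are heterogeneous, and this
  heterogeneity gives controls a small, realistic alarm base rate
  instead of a sterile zero. Draws are i.i.d. by default; an AR(1)
  switch exists for robustness experiments only.
* **Deterioration** in cases is a piecewise-linear drift toward
  abnormal targets (SBP 65, HR 135, RR 32, TEMP 38.8, GCS 3) with
  additive noise, active on a window positioned in hours before the
  event (default: the last 10 h). The drift ramps over the first 30%
  of the window and holds; after the window ends, fresh samples revert
  to baseline. This is the minimal mechanism that moves values across
  scoring bands at a controllable time.
* **Missingness** is whole-record dropout per parameter (default: GCS
  10%, vitals 0), exercising the screening rule that a record missing a
  mandatory vital is unscoreable.

`plant_window_signal()` repositions the drift window strictly inside
the prediction horizon, or strictly before it with a refresh gap long
enough (three mean inter-measurement intervals of the sparsest
parameter) that carried-forward abnormal values have been displaced by
fresh baseline measurements before the horizon opens. These placements
drive the parameter-recovery tests: an in-horizon signal must be
detected almost surely at the conventional threshold, a before-horizon
signal must not raise on-time alarms beyond the control base rate.

What the generator does *not* emulate: clinically clustered sampling,
autocorrelated or coupled physiology, measurement artefacts,
case-mix or treatment effects, and the empirical alarm base rate of any
particular hospital. Passing tests therefore demonstrate the internal
correctness of the scoring and evaluation machinery under controlled
conditions, not the clinical performance of MEWS on real data — results
published from protected EHR cohorts (AUCs, empirical alarm rates)
cannot be reproduced without those records and are not targets of this
package.

## Numerical choices and degenerate inputs

* Duplicate (patient, parameter, time) rows keep the last occurrence
  (EHR correction semantics) and log the collision; sorting is stable.
* Validation bounds (SBP 20--300 mmHg, HR 0--300 bpm, RR 0--80 /min,
  TEMP 25--45 °C, GCS integer 3--15) are configurable; rows violating
  them either error or drop, by policy.
* Interval indices and grids use small epsilons (1e-9) against
  floating-point drift; admission-time samples (t = 0) belong to the
  first interval.
* Windows in the bootstrap are closed; a control exactly $\tau$ long
  contributes windows anchored at 0.
* Undefined ratios are flagged `NaN`, never raised, so sweeps and
  reports survive extreme thresholds; the `undefined` column names the
  affected metrics.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise the pipeline at sizes
chosen to make Monte-Carlo assertions sharp while keeping a full run
comfortable on one CPU: 200-case cohorts for the planted-signal
recovery and sampling-rate checks, 1000 patients for the dropout
calibration, M = 2000 bootstrap windows against the exact
window-position oracle, 50--100 small cohorts for the whole-stay
equivalence sweep, and M = 1000 (the published choice) for the
end-to-end synthetic evaluation.

## A worked example

```{r example}
cfg <- eval_config(k = 4, tau = 12, tau0 = 0, m = 200, seed = 11)
cohort <- simulate_cohort(generator_spec(n_case = 30, n_control = 60,
                                         seed = 7))
ev <- evaluate_cohort(cohort, cfg)
ev
glance(ev)
tidy(ev)
```

Event-level numbers are read the same way as the published framework's:
`event_s` is the fraction of events with an actionable alarm inside the
12 h horizon, `fpr_boot` the probability that a random 12 h window in a
control recording contains a false alarm, and `wdr` the expected number
of work-ups per detected event.

```{r plots, fig.width = 6, fig.height = 4}
scores <- score_cohort(screen_scoreable(cohort), "base")
autoplot(threshold_sweep(screen_scoreable(cohort), scores), "roc")
```

## Known limitations

* The evaluation treats alarms as instantaneous and independent; alarm
  grouping, lockouts and escalation protocols are out of scope.
* MEWS presets beyond the standard table are not shipped (the
  configurable band table permits them, but no validated alternatives
  are bundled).
* The generator's clean separation of baseline and deterioration makes
  synthetic discrimination far better than anything achievable on real
  data; synthetic AUROCs near 1 are a property of the simulation, not a
  claim about MEWS.
* Statistical comparison between score variants (paired tests over
  patients) is not implemented; the framework reports the metrics
  themselves.
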