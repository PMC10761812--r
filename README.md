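# pdhbm — home-based monitoring analytics for Parkinson's motor fluctuations

Advanced Parkinson's disease patients on levodopa alternate between "ON"
periods of symptom relief and "OFF" periods of symptom recurrence (motor
fluctuations, MF). Smartwatch platforms can monitor this at home: a
free-living algorithm emits one binary tremor and one binary dyskinesia
detection per 30-s window and an activity score in [0,1] per 5-s window,
while a companion app collects medication-intake reports, 30-min symptom
diaries (ON / ON-with-dyskinesia / OFF / ASLEEP, 08:00–20:00), and daily
motor-task sessions (postural and rest tremor, pronation–supination,
finger tapping, timed-up-and-go) performed once OFF and once ON each day.

`pdhbm` is the analysis layer on top of those outputs, for digital-health
researchers and movement-disorder groups running two-week home-based
monitoring (HBM) protocols. It computes:

- **Compliance** — daily wear hours against the strict > 12 h rule,
  motor-task completion (≤ 2 missed of 28 sessions), reporting delay
  (median ≤ 30 min, ≤ 1 missed query), medication-intake adherence, and
  diary completeness (≥ 75% of slots within 2 h).
- **Free-living scores** — daily symptom prevalence
  `P_d = (# worn 30-s windows with a detection) / (# worn windows)`,
  daily mean activity, and per-patient overall scores (unweighted means
  over defined days), plus Spearman correlations with clinical items.
- **Diary ON/OFF statistics** — sensor measures aligned to the 30-min
  diary slots and Welch *t*-tests of ON vs OFF slots per patient, with a
  paired cohort-level summary (percent of patients higher in OFF / ON,
  percent significant).
- **Motor-task ON/OFF statistics** — per-state score summaries, Welch
  tests with metric-appropriate improvement directions, ±1 SD
  variability signatures, and validation against clinician ratings
  (0–4 ratings clamped to the watch's 0–2 scale).
- **Phase signatures** — each inter-dose interval split into 10
  equal-duration bins; per bin the tremor fraction and mean activity,
  averaged across all days. This normalizes the day onto the medication
  cycle and makes wearing-off tremor visible as peri-dose peaks.
- **Fluctuation profiles** — a transparent rule set over four features
  (overall prevalence P, phase-modulation index PMI, time-of-day index
  TDI, day-consistency C) assigns one of four profiles:
  `DOSE_RESPONSIVE`, `TIME_OF_DAY`, `CONSTANT`, `IRREGULAR`.
- **Raster plots** — one row per study day with tremor ticks, activity
  trace, medication lines, non-wear shading and diary backgrounds, each
  figure paired with a machine-readable sidecar JSON.

Because deposited patient data do not exist for this protocol, the
package ships a first-class synthetic cohort generator
(`simulate_patient()`, `simulate_cohort()`) that emulates the platform's
outputs for the four archetypes, with a latent trapezoidal
medication-effect curve driving tremor, dyskinesia and activity. Every
analysis stage is tested end-to-end against this generator's ground
truth.

## Worked example

```r
library(pdhbm)

params  <- archetype_params("DOSE_RESPONSIVE")   # 14 days, 5 doses/day
patient <- simulate_patient(params, seed = 7)
fit     <- hbm_analyze(patient)
print(fit)
#> <hbm_analysis P001>
#>   profile        : DOSE_RESPONSIVE
#>   features       : P = 0.37  PMI = 0.61  TDI = -0.07  C = 0.72
#>   overall tremor : 0.373   dyskinesia: 0.196   activity: 0.375
#>   diary tremor   : higher in OFF (p = 1.51e-11)
#>   wear > 12 h    : 100% of days

round(fit$signature$tremor[1, ], 2)   # first inter-dose interval
#>  [1] 0.83 0.72 0.22 0.07 0.05 0.06 0.06 0.14 0.72 0.83
```

Reading the output: this simulant spends 37% of worn time with tremor
overall (`P`), but the phase signature shows the tremor concentrated in
the bins just after (0.83, 0.72) and just before (0.72, 0.83) a dose,
with a quiet levodopa plateau in between — hence the high
phase-modulation index (`PMI = 0.61`, peri-dose minus mid-interval bins)
and the `DOSE_RESPONSIVE` label. The diary test confirms more tremor in
self-reported OFF slots. `plot(fit)` draws the raster;
`plot(fit, "phase")` draws the signature bars.

A cohort run mirrors the published tables' shape:

```r
cohort <- simulate_cohort(c(DOSE_RESPONSIVE = 10, TIME_OF_DAY = 10,
                            CONSTANT = 10, IRREGULAR = 10), seed = 42)
res <- hbm_analyze_cohort(cohort)
res$diary_summary    # group p, % higher in OFF/ON, % significant
res$task_summary     # ON/OFF means per task metric, % better in ON
res$profiles         # per-patient features and labels
```

There is also a command-line front end (`inst/cli/pdhbm`) with
`simulate`, `analyze`, `classify` and `report` subcommands.

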