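---
title: "Methods: home-based monitoring analytics for Parkinson's motor fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: home-based monitoring analytics for Parkinson's motor fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdhbm)
```

# The data model

`pdhbm` analyses the outputs of a smartwatch home-monitoring platform for
advanced Parkinson's disease, not the raw inertial signals. The inputs
are: binary tremor and dyskinesia detections, one per 30-s window; an
activity score in [0,1] per 5-s window (treated as an opaque intensity —
the platform does not define its physical meaning); a medication log of
scheduled dose slots and self-reported intake times; a two-day symptom
diary on a 30-min grid between 08:00 and 20:00; daily motor-task records
(scores 0–2, tap counts, times) with a self-reported ON/OFF session
state; and optional 0–4 clinician ratings.

All timestamps are naive local datetimes; daylight-saving arithmetic is
out of scope. Days split at local midnight. Every interval in the
package is half-open `[start, end)`; dose slots and phase bins are
1-based in outputs.

**Wear is inferred, not declared.** The watch emits a sample for every
window while worn, so non-wear appears as sampling gaps. A gap strictly
larger than `gap_threshold_s` (default three windows: 90 s for the 30-s
channels, 15 s for activity) splits worn intervals; each interval covers
its samples plus one trailing window. All prevalence denominators are
restricted to worn time.

# Scores and statistics

*Daily prevalence* is the fraction of worn 30-s windows with a
detection; days with under `min_bins_per_day` worn windows (default 120,
one hour) are undefined and excluded. The *overall* score is the
unweighted mean over defined days — each day carries equal weight
regardless of wear duration, which matches the protocol's day-centric
reporting; a bin-weighted alternative would over-weight long-wear days.

*Diary alignment* computes, per filled 30-min slot, the tremor and
dyskinesia percent and mean activity over worn time; slots worn less
than 50% (`min_slot_coverage`) are excluded. ON and ON-with-dyskinesia
slots are pooled as ON for the binary comparison (a separate ON_DYSK
stratum is available via `pool_dysk = FALSE`); ASLEEP slots are dropped.

*Tests.* The protocol's "unpaired t-tests" are implemented as Welch by
default — slot counts and variances differ freely between states — with
the pooled-variance Student variant behind `var_equal = TRUE`. The
cohort-level diary comparison is a paired t on per-patient (ON mean,
OFF mean), since every participant contributes both states; an unpaired
pooling variant is available (`paired_cohort = FALSE`). Alpha defaults
to 0.05 two-sided with no multiple-testing correction, mirroring
per-patient significance reporting; `bonferroni_m` divides alpha when a
correction is wanted. Degenerate inputs (fewer than 2 observations per
group, zero-variance groups, constant rank vectors) return a result
flagged `undefined` instead of throwing, so one pathological patient
cannot abort a cohort run. Rank correlations use midranks.

*Motor tasks.* A session is one (day, state) pair; duplicate same-state
sessions on a day count once. The completion rule (28 sessions, at most
2 missed) counts sessions, not task types — the protocol wording is
ambiguous, so a per-task-type mode exists (`per_task_type = TRUE`).
"Better in ON" is metric-specific: more valid taps, shorter inter-tap
time, shorter TUG time, lower tremor/bradykinesia scores. The
variability signature flags sessions differing from the patient's task
mean by strictly more than one SD. Clinician 0–4 ratings collapse to
the watch's 0–2 scale as `min(raw, 2)`. Whether a patient "shows
tremor" in a task defaults to *any session score > 0* (configurable to
mean > 0); the source protocol leaves this unstated.

*Compliance boundaries* are read literally: "more than 12 h" is strict
(a 12.0-h day fails), "at least 75%" and "no more than 2 / 1" are
inclusive, and a diary report at exactly the 2-h deadline counts. The
daily prompted queries share the diary reporting channel, so unanswered
diary slots stand in for missed queries.

# Phase normalization

Each day's inter-dose intervals run between consecutive *reported*
intakes — the raster marks actual intake times, and anchoring to
schedule would smear the wearing-off peak by the reporting delay.
Intervals adjacent to a skipped (unreported) dose are invalid for that
day; a day needs at least two reported doses. The interval after the
last dose is bounded by the end of worn time that day, capped at
`max_final_h = 6` h (the protocol never bounds the tail; six hours spans
a typical evening without letting a sparse tail dominate).

Every valid interval is split into 10 equal-duration bins; a sample
belongs to the bin containing its start timestamp (half-open bins; ties
are impossible on the 30-s grid). Per bin: tremor fraction =
detected / worn samples, activity = mean of worn 5-s values; cells with
worn coverage below 10% of the bin duration are missing. Day matrices
are averaged cellwise, aligned by scheduled slot index, over the days
where each cell is defined — so a patient who removes the watch after
dose 4 on most days simply has the later intervals drop out of the
average rather than biasing it. Conservation (every worn sample in the
dosing span lands in exactly one cell) and exact agreement with a
per-sample brute-force assignment are tested properties.

# The fluctuation-profile classifier

The published grouping of MF patterns was done by visual inspection;
the quantitative rule set here is this package's own construct,
validated only against synthetic ground truth. Four features:

- **P** — overall tremor prevalence in [0,1];
- **PMI** — phase-modulation index: per signature row, mean tremor in
  the peri-dose bins {9, 10, 1} minus the mid-interval bins {4–7},
  averaged over rows with ≥ 8 defined cells. Bins 9–10 catch the
  wearing-off rise before the next dose and bin 1 the pre-onset lag
  after it; bins 4–7 sit on the levodopa plateau.
- **TDI** — time-of-day index: afternoon (12:00–20:00) minus morning
  (08:00–12:00) prevalence, averaged over days with both halves worn
  (≥ 5 days required);
- **C** — day-consistency: mean pairwise Pearson correlation between
  days' 24-h profiles over hours defined in both; identically flat
  pairs count as 1, half-constant pairs are skipped.

Ordered rules (defaults in parentheses): (1) `P ≥ 0.60` and
`PMI < 0.15` → CONSTANT; (2) `PMI ≥ 0.15` → DOSE_RESPONSIVE; (3)
`|TDI| ≥ 0.20` and `C ≥ 0.30` → TIME_OF_DAY; (4) otherwise IRREGULAR.
CONSTANT precedes DOSE_RESPONSIVE because high-prevalence patients can
show small spurious phase contrasts; TIME_OF_DAY requires consistency
so that a single skewed day cannot mimic a part-of-day pattern. Any
undefined feature yields UNCLASSIFIABLE with the reason. All thresholds
are surfaced in `profile_thresholds()`.

`threshold_sensitivity()` reports archetype recovery under ±25%
perturbation of each threshold. The PMI/TDI/C cutoffs sit in wide
margins; `theta_const` is the sensitive one — CONSTANT-type feature
vectors concentrate near P ≈ 0.7, so raising the cutoff from 0.60 to
0.75 crosses them. That sensitivity is a property of the rule set worth
knowing, not a defect the report hides.

# The synthetic cohort generator

The generator defines the study conditions: 14 days, 5 daily doses
evenly spaced 08:00–20:00 (3–9 supported), ~14 h daily wear (jittered
08:00–22:00 window, occasional ~45-min midday gaps), two non-consecutive
diary days, and one OFF plus one ON motor-task session per day.

A latent medication-effect level `E(t) ∈ [0,1]` drives all channels.
Within each inter-dose interval `E` follows a trapezoid: zero during a
30-min absorption lag, linear onset over 15 min, full effect until 75%
of the interval, linear wearing-off over 15 min — the simplest shape
producing peri-dose tremor peaks, deliberately not a pharmacokinetic
ODE. Tremor detections are Bernoulli with
`p(t) = p_off·(1−E) + p_on·E` (defaults 0.8 / 0.05), dyskinesia
analogously but ON-coupled (0.3 / 0.05), and activity is a linearly
declining daily baseline (0.6 → 0.3, matching the common end-of-day
activity drop) minus 0.2 times the concurrent tremor detection, plus
Gaussian noise (sd 0.05). A bin is latent-ON when `E ≥ 0.5`.

Archetypes modify `E`: TIME_OF_DAY keeps dose coupling before
`switch_hour` (12:00) and forces persistent tremor after it, with a
milder `p_off = 0.6` so the overall prevalence stays clearly below the
CONSTANT regime; CONSTANT sets `E = 0` except for 2 random ~45-min
dose-independent quiet blocks per day; IRREGULAR runs a per-day
two-state Markov chain (dwell ~45 min) whose stationary tremor
probability is resampled daily from U(0.2, 0.7), so no pattern repeats
across days.

Reported intakes are scheduled times plus a normal delay (mean 10, sd
10 min) truncated to [−15, 60] min — the cap also guarantees reported
times stay ordered at the densest 9-dose schedule — and doses are
skipped with probability 0.03. Diary states derive from the majority
latent label per slot with a 10% flip probability, ON_DYSK when the
slot's dyskinesia prevalence exceeds 0.3, and 5% missing slots.
Motor-task scores are drawn from the published cohort-level
distributions (valid taps ON 34.4 ± 6.6 / OFF 24.6 ± 8.2; inter-tap
time 0.29 ± 0.06 / 0.4 ± 0.13 s; TUG 17 ± 3.6 / 21.68 ± 4.42 s) and
from separation-chosen tremor/bradykinesia score normals clipped to
[0, 2].

What the generator does **not** emulate: tremor severity (only
occurrence), pharmacokinetic variability between doses, sleep, sensor
artefacts, false detections during voluntary movement (a known
confounder of real dyskinesia channels), or correlations between
compliance behaviour and symptom state. Passing tests therefore show
that the pipeline recovers structure *of the kinds encoded here*; they
are not clinical validation.

# Determinism and problem sizes

Everything randomized takes an explicit seed; per-patient seeds derive
deterministically from the cohort seed, and `simulate_patient()`
restores the caller's RNG state. The test suite runs the oracle
comparisons on 100 random synthetic days, the classifier recovery on
the default 40-patient cohort (seed 42), the diary power check on 200
shifted and 2000 null replicates, and the task-score recovery on a
20-patient cohort — sizes chosen so the whole suite completes in a few
minutes while keeping Monte-Carlo error well inside the asserted
margins.

# Known limitations

- The activity channel is opaque; results about it describe the score,
  not bradykinesia.
- The classifier thresholds are calibrated on the generator's archetype
  geometry; real cohorts will need re-tuning (`theta_const` above all).
- The cohort-level "percent of patients" summaries are over patients
  with defined tests, so denominators can differ between measures.
- Diary self-reports are taken at face value; no smoothing or
  state-inference is applied.
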