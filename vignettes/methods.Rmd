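---
title: "Methods: activity-pattern metrics and matched-cohort screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-pattern metrics and matched-cohort screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actipat)
```

## Scope and design

`actipat` analyses epoch-level wrist-accelerometer recordings in a
case-control design motivated by rheumatoid arthritis (RA). Its inputs are
a uniform grid of 30-second acceleration-magnitude epochs (ENMO, in
milligravities) with a wear mask, optionally paired with per-epoch
activity-state labels, plus a participant table of demographics and
covariates. Because the kind of biobank actigraphy this design targets is
access-restricted, the package ships a first-class synthetic generator
that emulates the statistical structure the analysis relies on; every
downstream stage is developed and tested against it.

## The synthetic generator

### State process

Activity states (sleep, sedentary, light, MVPA, walking) follow a
semi-Markov process on the epoch grid. At each state entry at hour-of-day
$h$, the next state $s$ is drawn with probability proportional to
$w_s \cdot c_s(h)$, where $w_s$ is a baseline entry weight and

$$c_s(h) = \exp\!\big(a_s \cos\big(2\pi (h - \phi_s)/24\big)\big)$$

is a strictly positive circadian multiplier with per-state amplitude $a_s$
and peak hour $\phi_s$. The sojourn in $s$ is geometric on epochs with
mean $m_s \cdot c_s(h)^{\gamma}$; the exponent $\gamma = 0.4$ dampens the
sojourn modulation so that entry timing, not run length, carries most of
the circadian signal — with undampened modulation, nocturnal sleep runs
drawn near the circadian peak would routinely exceed twelve hours.
Consecutive sojourns may re-enter the same state, so observed runs are
mixtures of geometric sojourns. This is deliberately the simplest model
producing (i) realistic run-length structure for the fragmentation
metrics, (ii) consolidated nocturnal sleep, and (iii) configurable
occupancy per state.

Defaults were chosen once to produce, at 7 days × 2,880 epochs/day, a
population that a field practitioner would call plausible: about 8.5 h/day
of sleep-labeled time (including naps), ~45% sedentary occupancy, and
45–60 minutes/day above the 100 mg MVPA cutpoint, with sleep concentrated
between roughly 23:00 and 07:30. Demographics default to the marginals of
a large RA actigraphy population (about 75% aged 60 or over, 67% female;
ADI mean −1.48, SD 2.88), with configurable group imbalances in smoking,
alcohol, chronotype, season and work status so covariate adjustment is
exercised. Two log-normal latent traits per participant (overall activity
level, geometric SD 1.22; MVPA propensity, geometric SD 1.42) provide the
between-participant heterogeneity that gives the screening stage a
realistic variance structure; without them, between-participant variation
would collapse to Monte-Carlo noise and screening power would be
unrealistically high.

### Magnitudes, non-wear, interruptions

Conditional on its label, each epoch's magnitude is log-normal with
per-state median and geometric SD (sleep 8 mg ×/1.6, sedentary 18 ×/1.7,
light 55 ×/1.3, walking 130 ×/1.25, MVPA 165 ×/1.35). Medians respect the
40/100 mg cutpoint semantics: light mostly lies in 40–100 mg, walking and
MVPA mostly above 100. The light-state geometric SD is kept tight enough
that the light tail above 100 mg stays a negligible share of measured
MVPA time — this is what makes the RA effect knob below mean what it
says. Non-wear episodes arrive as a Poisson process (default 0.2/day,
mean 120 min) and are labeled, masked, and given an on-table signal.
Brief nocturnal movement episodes interrupt sleep runs at a configurable
rate (default 1.5/h of sleep, mean 2 min), fragmenting sleep the way
restlessness does.

### RA effects

The `ra_effect()` bundle encodes the qualitative RA findings as
generative knobs:

* `mvpa_time_ratio` (default 0.7) — ratios below 1 are realized by
  *binomial thinning*: each MVPA or walking run is replaced by sedentary
  time with probability $1 - \rho$. Thinning scales expected measured
  MVPA time by exactly $\rho$ and leaves the surviving run-length
  distribution untouched. Two alternatives were rejected during design:
  scaling entry weights under-delivers (the renormalization of entry
  probabilities dilutes a nominal 0.8 to ~0.83 measured), and
  compensated probability scaling over-delivers (~0.77) because occupancy
  depends on the sojourn-weighted denominator. Walking runs are included
  because walking magnitude lies in the MVPA range; a knob that altered
  only the MVPA-labeled state would not govern measured (≥ 100 mg) MVPA
  time.
* `mvpa_run_ratio` (default 0.85) — multiplies the MVPA mean sojourn,
  shortening sustained MVPA without changing how often it is attempted.
* `morning_delay_minutes` (default 45) — MVPA/walking entry rates ramp
  linearly from ~0 to full over this interval after the nocturnal phase
  ends (taken as the sleep circadian peak + 6 h).
* `sleep_interrupt_rate_ratio` (default 1.5) — multiplies the nocturnal
  movement-episode rate.

Each knob touches exactly one generative component, which the test suite
verifies (e.g. halving `mvpa_run_ratio` halves MVPA run lengths but
leaves mid-sleep clock time unchanged).

### What the generator does not emulate

Raw 100 Hz tri-axial signals, device calibration drift, weekday/weekend
behavioural differences, seasonal activity trends, medication effects,
and correlation between demographics and activity (age does not lower
simulated MVPA). Consequently, passing tests demonstrate that the
*pipeline* recovers what the generator injects — not that real RA
populations would show these effect sizes.

## Preprocessing choices

Magnitude is ENMO: $\max(0, \sqrt{x^2+y^2+z^2} - 1000)$ mg, the
convention of the standard large-cohort wrist protocol. Non-wear is any
epoch inside a ≥ 60-min window with magnitude SD below 13 mg; the rule is
idempotent and applied to magnitude only, so single-channel data are
supported. Validity requires ≥ 72 h of total wear, evaluated as a simple
total with no per-hour coverage requirement (a stricter coverage mode can
be layered on by the caller); the boundary is inclusive at exactly
72.0 h. Non-wear epochs are imputed by the same-time-of-day mean across
wear days for magnitude metrics; label-based metrics instead exclude
non-wear epochs. A time-of-day slot with no wear data anywhere is an
error naming the slot, since its mean is undefined.

## Labeling and night consolidation

When external activity labels exist they are ingested as-is; otherwise
the fallback labeler applies the 40/100 mg cutpoints and relabels
sustained quiescence (sedentary runs ≥ 30 min with mean < 10 mg) as
sleep. The night-time lying-down window is consolidated per noon-to-noon
night: initialize at the longest sleep run, extend each edge in 30-min
blocks while the adjacent block is ≥ 50% sleep, stop when neither edge
moves, then trim to sleep epochs. The block length and threshold are
configurable; this concrete rule stands in for iterative sleep-window
consolidation procedures whose details vary across implementations.
Nights are noon-to-noon so a sleep period is never split; the first and
last partial days contribute no night metrics. The get-up time is the end
of the consolidated window. Ambulatory bouts are maximal walking runs
allowed to bridge a single break — one epoch (30 s) for bouts in the
2–10 min class, two epochs (1 min) for longer classes — where the class
is decided by the merged duration; bouts must start and end on walking
epochs.

## Bout semantics

A bout for a predicate (sedentary < 40 mg, active 40–<100 mg,
MVPA ≥ 100 mg) is a maximal interval whose boundary epochs are compliant,
whose internal non-compliant runs each last at most the break tolerance
(default one epoch), and whose duration reaches the minimum (active
10 min, MVPA 3 min). The production detector merges compliant runs across
small gaps on a run-length encoding; `oracle_bouts()` independently
re-derives the set by scanning forward from every compliant epoch, and a
property test asserts exact agreement on a thousand random sequences
across tolerances 0–2 and minimum durations 3–10 min. Non-wear epochs are
non-compliant for every predicate and break bouts regardless of
tolerance. Sedentary bouts are the wear-time complement of the active
bouts, so sedentary-bout time plus active-bout time equals wear time
exactly.

## The metric registry

The registry is the single source of truth: 147 domain registrations over
145 unique metrics — total volume 77, morning 30, night 15, fragmentation
25 — with exactly two metrics registered in two domains each (the M10
mean level in total volume + night; MVPA percent of wear time in total
volume + fragmentation). Daily statistics are computed per calendar day
then averaged (or SD'd) across days; weekly totals are mean daily values
× 7; weekday/weekend follow the ISO calendar, so metric values are
invariant to shifting a recording by whole weeks (not arbitrary whole
days). Clock-time metrics (sleep midpoint, L5/M10 midpoints) are hours
since midnight in [0, 24) with circular averaging across nights. L5/M10
are rolling 5-h/10-h means over the across-day average 24-h profile
(computing per-day extremes and then averaging is more variable and is
left to the caller). Hazards use the censoring rule: a run truncated by
the recording end or a non-wear gap has no observed exit, so it is
excluded from the hazard's mean completed run length but kept in the
run-duration descriptives; the between-state transition probability keeps
censored epochs in its denominator (matching the hand-count definition)
but is reported missing when no completed run exists at all, since an
exit rate is then unidentified. Rest fragmentation with zero movement
episodes is defined as 0 (a perfectly quiet night is unfragmented).

## Matching

Cases are processed in seeded random order; each takes its `ratio`
(default 2) nearest available controls without replacement, with distance
infinite across sexes and otherwise the sum of absolute category-index
differences over 5-year age bin, BMI class (18.5/25/30/40 edges), and ADI
quintile (edges from the case group's empirical distribution, applied to
both groups). The default caliper in `match_config()` is 0 — exact
category matching, which also explains why a case can fail to match. The
pipeline demo uses a caliper of 2 steps because its control pool is only
4:1; published biobank analyses draw on pools closer to 80:1, where exact
matching almost always succeeds.

## Screening, adjustment, and PCA

Metric values are log-transformed per group; zeros are offset by half the
smallest positive observed value (configurable). The screen reports the
geometric-mean ratio with a Welch 95% CI on the log-mean difference
(the unequal-variance interval is the conservative default when no method
is prescribed) and flags a metric when |ratio − 1| > 0.05 *and* the CI
excludes 1. Clock-time metrics are screened on the linear scale with an
arithmetic-difference CI — a log ratio of clock times is meaningless —
and flagged when the CI excludes 0; the registry tags these metrics.
P-values from ANOVA/ANCOVA are exploratory and unadjusted for
multiplicity by default; `p.adjust` can be applied by the caller and any
such output should be labeled as an extension. ANCOVA fits one covariate
at a time (log value ~ covariate + group) and tests the group term last,
matching per-covariate reporting; a joint model is a one-line extension.
PCA drops metrics with any missing value (recorded), standardizes columns
to mean 0 / SD 1, and reports loadings, scores, and variance fractions;
the suggested component count is the smallest reaching 70% cumulative
variance.

### Calibration and recovery checks

Two simulation checks validate the screening stage end to end, at sizes
chosen for desk-scale runtimes:

* **Null calibration**: 500 independent metric screens, each with 300
  cases and 600 controls drawn from one log-normal distribution
  (geometric SD 1.49, matching the between-participant spread of the
  synthetic MVPA time metrics). The 95% CI excludes 1 in ~5% of screens,
  and the flagged fraction can only be smaller because flagging adds the
  magnitude rule. Independent screens are simulated directly — one
  cohort's 145 metrics cannot supply 500 independent screens, and the
  screen, not the generator, is the unit under test here.
* **Effect recovery**: 200 replicate cohorts of 75 cases vs 150 controls,
  each participant a full 7-day simulation, cases carrying a pure
  `mvpa_time_ratio = 0.8`. The daily-MVPA-minutes screen's CI covers 0.8
  in ≈ 95% of replicates and ≈ 98% of the eight MVPA time-family metrics
  are flagged per replicate. The family excludes MVPA *magnitude* and
  *run-length* metrics by construction: a time-rate knob does not move
  them, and their inclusion would misrepresent recovery.

## Numerical and degenerate-input conventions

Geometric sojourn means below one epoch are clamped to one epoch. A
geometric SD of exactly 1 degenerates the magnitude distribution to the
state median. Rolling L5/M10 means wrap circularly via a doubled profile;
time-of-day slots never observed fall back to the overall mean so the
rolling window stays defined. Ties in matching distances resolve by pool
order, making matching fully deterministic given the seed. All random
stages take explicit seeds and restore the caller's RNG state.

## Known limitations

Single recording per participant; timezone-naive local time with no DST
handling; the HAR model that produces real activity labels is out of
scope (the cutpoint fallback is a deliberately crude stand-in); the
night-window expansion rule is a reasonable but non-canonical
reconstruction; and the synthetic cohort's demographics are independent
of its activity process, so demographic confounding is exercised only
through the configurable covariate imbalances, not through causal paths.
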