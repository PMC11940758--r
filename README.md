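# actipat

Wrist-actigraphy activity patterns in rheumatoid arthritis (RA) cohorts:
from epoch-level accelerometer magnitude to a 145-metric catalogue of
physical-activity pattern measures, matched case-control screening, and
principal component analysis — with a synthetic-data generator that stands
in for restricted-access biobank actigraphy so the entire analysis runs,
tested, on any machine.

## The problem

RA symptoms — pain, fatigue, morning stiffness — are hard to quantify with
questionnaires. Wrist accelerometers record them indirectly as altered
patterns of daily activity: less moderate-to-vigorous physical activity
(MVPA), delayed morning activity, fragmented sleep, and difficulty
sustaining activity. This package implements the full analysis chain a
biostatistician needs to screen such digital measures in a case-control
design:

1. **Preprocessing** — ENMO magnitude
   (`max(0, ||(x,y,z)|| − 1000)` mg), 30-s epoch aggregation, non-wear
   detection (60-min windows with SD < 13 mg), same-time-of-day
   imputation, and the 72-hour wear-time validity criterion.
2. **Labeling** — per-epoch activity states (sleep / sedentary / light /
   MVPA / walking), a cutpoint fallback labeler (40 / 100 mg), consolidated
   night-time lying-down windows (longest sleep run, extended in 30-min
   blocks while ≥ 50% sleep), get-up times, and ambulatory bouts
   (2–10 / 10–30 / >30 min with a single class-dependent break).
3. **Bouts** — sustained-activity bouts: maximal intervals with compliant
   boundaries, internal breaks no longer than the tolerance (default one
   30-s epoch), and duration above the minimum (active ≥ 10 min,
   MVPA ≥ 3 min); verified epoch-by-epoch against a brute-force reference
   detector.
4. **Metrics** — a canonical registry of 145 unique metrics (147 domain
   registrations) over four domains: total volume of activity (77), morning
   activity (30), night-time activity (15), and fragmentation of activity
   (25), including L5/M10 circadian timing, sleep efficiency, rest
   fragmentation, and state-transition hazards
   `h(A→B) = 1 / E[completed run length of A]`.
5. **Cohort** — eligibility filters (comorbidities, rheumatoid factor
   > 20 IU/mL in controls, post-recording diagnoses) and 2:1
   nearest-neighbour matching without replacement on sex, 5-year age bin,
   BMI class, and ADI quintile.
6. **Statistics** — per-metric screening on the log scale: the
   geometric-mean ratio `exp(mean(log x_RA) − mean(log x_ctrl))` with a
   Welch 95% CI, flagged when `|ratio − 1| > 0.05` and the CI excludes 1;
   one-way ANOVA and single-covariate ANCOVA on log values; wake-aligned
   population activity profiles; standardized PCA.
7. **Synthetic data** — a circadian semi-Markov generator (geometric
   sojourns, 24-h modulated entry rates, label-conditional log-normal
   magnitudes, non-wear and sleep-interruption processes) with injectable
   RA effects whose knobs are calibrated to mean what they say (an
   `mvpa_time_ratio` of 0.8 yields 0.8× the expected measured MVPA time).

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (40 RA, 160 control pool, 7-day recordings; deterministic seed):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_metrics.R
Rscript analysis/03_match.R
Rscript analysis/04_screen.R
Rscript analysis/05_profiles.R
Rscript analysis/06_pca.R
```

which prints, among other things:

```
simulated 176 participants (37 RA, 139 control pool)
recordings meeting the 72-h wear criterion: 176 / 176
mean daily MVPA minutes: RA 33.9 vs control 56.8
mean sleep efficiency: RA 92.9% vs control 95.0%
caliper-2 matching: 35 / 37 cases matched
screened 144 metrics; 101 flagged (|ratio-1| > 5% and CI excluding 1)
mean RA-control MVPA probability difference, first 2 h after wake: -0.0329
variance fractions: PC1 48.5%, PC2 11.3%, PC3 5.7% (cum 65.5%)
PC1 top loadings: time_ge100_daily_min, mvpa_pct_wear, weekly_mvpa_min
```

The injected RA effect bundle (MVPA time ×0.7, MVPA run length ×0.85,
45-min morning delay, 1.5× sleep interruptions) surfaces exactly where it
should: MVPA-related metrics carry the smallest RA/control ratios, the
morning-window MVPA metrics are the most depressed, and the first
principal component is dominated by overall MVPA volume. Tables land in
`results/`.

Programmatic use mirrors the scripts:

```r
library(actipat)
res <- run_pipeline(run_config(seed = 1, n_ra = 30, n_pool = 120))
head(res$screen[res$screen$flagged, ])
```

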