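---
title: "Methods: rhythmicity, sleep scoring and the synthetic forager model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythmicity, sleep scoring and the synthetic forager model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythm)
```

`actirhythm` analyses per-minute activity counts from insect foragers —
beam-break counts for bees isolated in monitor tubes, or foraging-trip
events for bees observed within a colony — recorded through a block of
12 h:12 h light:dark entrainment (LD) followed by constant darkness (DD).
This vignette documents the statistical model behind each stage, the
parameters a user may want to change, and the choices made where more than
one defensible convention exists.

## The phase model

A `light_schedule` maps any timestamp to one of four phases. During the LD
block, minutes in `[lights_on, lights_on + 720)` are *day* and the rest
*night*; during the DD block the same 24 h partition, extrapolated from the
entrained lights-on time, defines *subjective day* and *subjective night*
(the half that was dark during entrainment). Two conventions are fixed here
because monitor data leave them ambiguous:

- **Half-open intervals.** A boundary timestamp belongs to the phase it
  begins: the lights-off minute is the first minute of night. This makes the
  four phase slices an exact partition — per-phase activity sums reconstruct
  the total with integer equality, which the test suite asserts.
- **Bin midpoints.** When the series is binned coarser than 1 min, a bin's
  phase is that of its midpoint. Because bin widths must divide 1440 min,
  bins never straddle a phase boundary under an aligned schedule, so the
  midpoint rule is unambiguous rather than approximate.

Only 12:12 photoperiods are supported; dawn/dusk ramps and light-intensity
effects are out of scope.

## Rhythm strength

Rhythmicity is quantified on 30-min bins (the same granularity as the sleep
profile, and standard for insect actograms). The sample autocorrelation

$$r_k = \frac{\sum_{i=1}^{N-k}(y_i-\bar y)(y_{i+k}-\bar y)}
             {\sum_{i=1}^{N}(y_i-\bar y)^2},\qquad k = 0,\dots,K$$

uses a lag-independent denominator, which guarantees $r_0 = 1$ and
$|r_k|\le 1$. The circadian peak is the highest *interior local maximum* of
$r_k$ in an 18–30 h lag window (falling back to the window maximum if the
correlogram is monotone there). Peak-picking by local maximum rather than by
the literal third peak of a symmetric correlogram is robust to noisy
side-lobes; for clean circadian data the two coincide. The rhythmicity
statistic is the peak height scaled by the 95 % white-noise confidence line
$2/\sqrt N$:

$$\mathrm{RS} = \frac{r_{\text{peak}}}{2/\sqrt N},$$

with RS ≤ 1.5 classified arrhythmic (the threshold is inclusive on the
arrhythmic side) and the peak's lag taken as the period estimate. LD and DD
blocks are always analysed separately, never pooled, since masking by light
can produce apparent rhythmicity unrelated to the endogenous clock.

Numerical edge cases: a constant (zero-variance) series has no defined
autocorrelation; `autocorrelogram()` refuses it, and the `rhythmicity()`
wrapper classifies it arrhythmic with `rs = 0` and a `constant_series` flag.
Recording blocks shorter than twice the 48 h default maximum lag have their
maximum lag shrunk to half the data (never below the 30 h top of the search
window). Ties between equal-height local maxima resolve to the shortest lag,
making period estimates deterministic.

Tunable settings (config/arguments): analysis bin width (30 min), maximum
lag (48 h), search window (18–30 h), RS threshold (1.5).

## Sleep scoring

Sustained inactivity of at least five minutes is the standard proxy for
insect sleep; "longer than 5 min" is implemented as run length ≥ 5, matching
the proxy literature's convention, with the threshold configurable. Scoring
demands genuine 1-min bins — a rebinned series cannot be un-summed, so
`detect_sleep_bouts()` rejects coarser input rather than silently rebinning.
Bouts are maximal zero runs, hence non-overlapping, and detection is
idempotent.

Summaries attribute each *episode* to the phase where it started (episode
counts answer "how many sleep episodes were initiated in the day?") while
splitting its *minutes* across the phases it spans, so
`total_sleep_day + total_sleep_night` always equals the total in-regime
sleep — an exact conservation the tests enforce. Sleep is summarised for the
LD block by default (day/night figures); the DD block is available via
`regime = "dd"`. Group-level comparisons use per-day means (totals divided
by the number of analysed days), the reading adopted here since totals and
per-day means differ only by the fixed day count within a balanced design.
A phase with zero episodes reports its mean bout length as missing, not
zero, to avoid biasing group means downward.

## The synthetic forager

The generator exists so that every pipeline stage can be validated against
known ground truth. Each subject is an inhomogeneous counting process gated
by a two-state sleep/wake chain, simulated per minute over
`n_days_ld + n_days_dd` days (default 5 + 5, lights on at midnight):

- While **awake**, the count rate is
  $\lambda(t) = \text{base\_rate}\,(1 + A\cos 2\pi (t - \phi)/\tau)$ with
  modulation depth $A \in [0,1]$, acrophase $\phi$ (default 06:00, the
  middle of the photophase) and period $\tau$ (default 24 h). Counts are
  drawn from a **zero-truncated** Poisson law with that rate, so an awake
  minute always shows at least one count. Truncation is what makes
  zero-count runs coincide exactly with the simulated sleep state: detected
  bout counts and totals can then be compared to ground truth with exact
  integer equality, for any seed. The price is a mean awake count of
  $\lambda/(1-e^{-\lambda})$ rather than $\lambda$, which the tests use as
  the reference value; at the default rates the difference is ≈ 0.3
  counts/min.
- **Sleep onset** is a per-minute hazard that differs between (subjective)
  day and night; bout durations are geometric with mean `mean_bout_min`
  (default 20 min, a realistic bumblebee bout scale). Sleep fully
  suppresses counts. A sinusoid (rather than a square wave) was chosen as
  the simplest rate structure satisfying the autocorrelation analysis'
  assumptions; light-masking multipliers are not modelled.

The three treatment presets (`control`, `imidacloprid_1`,
`imidacloprid_10`, versioned in `inst/extdata/treatment_presets.yaml`)
encode the *directions* of neonicotinoid effects — progressively weaker
modulation (0.8 → 0.5 → 0.25), lower awake base rate (2.0 → 1.7 → 1.4
counts/min) and higher daytime sleep-onset hazard (0.004 → 0.010 → 0.020
per min) with unchanged bout length, so daytime sleep rises through *more
episodes*, not longer ones. The numbers are generator conventions chosen
once to produce a clearly rhythmic control cohort and a near-threshold
high-dose cohort; they are not measurements.

What the generator does *not* emulate — and hence what passing tests cannot
show about real recordings: between-subject parameter heterogeneity,
light-masking and startle responses, drug-induced immobility that mimics
sleep, ultradian bout structure, missing bins and monitor dropouts, and the
social modulation of foraging within a colony. Conclusions about real data
rest on the correctness of the computations, not on the realism of the
synthetic cohorts.

Determinism: every subject derives from a single integer seed; cohorts
derive per-subject seeds from one master seed, and all simulation runs
restore the caller's RNG state.

## Group statistics

Figure-style endpoints are compared with classical fixed-effects one-way
ANOVA (between df $k-1$, within df $N-k$) followed by Tukey HSD using the
studentized-range law with the Tukey–Kramer correction for unequal group
sizes; two-group comparisons use Student's pooled t by default (matching the
$n_a+n_b-2$ degrees of freedom conventionally printed for such monitor
studies), with Welch's correction behind a flag. All tests are two-sided at
α = 0.05; descriptive output is mean ± SEM with sample-sd/√n. Proportions of
arrhythmic subjects are reported descriptively, without a test. The suite
verifies the F statistic against a literal sum-of-squares oracle, the
$F = t^2$ identity for two groups, Tukey dominance over unadjusted pairwise
p values, and a ≈ 5 % type-I error rate over 1,000 simulated null cohorts.

## Validation problem sizes

The packaged checks run on cohorts sized to exercise the statistics at the
scale of a typical monitor experiment: 100 seeded subjects per amplitude
condition for classification (amplitude 0.9 → ≥ 95 % rhythmic; amplitude
0 → ≥ 85 % arrhythmic) and period recovery (±0.5 h of 24 h, the lag
resolution of 30-min bins), 50 random 10-day series for agreement between
the fast autocorrelogram and an $O(N^2)$ direct-sum oracle (within 1e−9),
and 20-subject groups for the end-to-end pipeline bundle.

## Known limitations

The 5-min inactivity proxy cannot distinguish sleep from drug-induced
immobility; the pipeline reports inactivity-defined sleep and leaves that
interpretation to the analyst. Period estimation inherits the 30-min lag
grid (±0.5 h resolution) and the peak-picking window; free-running periods
outside 18–30 h require widening the window. Missing bins are not imputed —
monitor files with timestamp gaps are rejected at ingestion — and
photoperiods other than 12:12 are unsupported.
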