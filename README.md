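# actirhythm

Circadian rhythmicity and sleep analysis for insect activity-monitor data.

Behavioural chronobiologists studying pollinators record per-minute activity
counts — beam breaks for bees isolated in monitor tubes, or foraging-trip
events at a colony entrance — across a block of 12 h:12 h light:dark (LD)
entrainment followed by constant darkness (DD). `actirhythm` turns those raw
count series into the standard analysis endpoints of such studies:

- **Rhythm strength.** The autocorrelogram of the 30-min-binned series,
  `r_k = Σᵢ (yᵢ − ȳ)(yᵢ₊ₖ − ȳ) / Σᵢ (yᵢ − ȳ)²`, is searched for its circadian
  peak (highest local maximum at lags 18–30 h). The **rhythmicity statistic**
  is the peak height divided by the 95 % white-noise confidence line
  `2/√N` (N = bins analysed): `RS = r_peak √N / 2`. Subjects with RS ≤ 1.5
  are classified **arrhythmic**; the peak's lag estimates the period τ.
- **Sleep.** Any maximal run of ≥ 5 min of zero counts is scored as a sleep
  bout (the conventional insect-sleep proxy). Episodes are attributed to the
  day or night phase in which they were *initiated*; their minutes are
  apportioned to the phases they actually occupy, so per-phase totals are
  exactly conserved.
- **Phase partition.** Every timestamp maps to day/night (LD) or subjective
  day/subjective night (DD, extrapolating the entrained lights-on time), with
  half-open `[lights-on, lights-off)` intervals.
- **Group statistics.** Mean ± SEM, one-way ANOVA with Tukey's multiple
  comparisons, and pooled or Welch two-sample t tests.
- **Actograms, monitor I/O, and a seeded synthetic generator** of forager
  cohorts with known circadian/sleep ground truth, including treatment
  presets that emulate neonicotinoid-like effects (weaker rhythm, less
  daytime activity, more daytime sleep episodes).

## Worked example

```r
library(actirhythm)

# one synthetic control forager: 5 LD + 5 DD days, lights on at midnight
sim <- simulate_forager(treatment_preset("control", seed = 42),
                        subject_id = "bee01")

rhythmicity(sim$series)
#> <rhythmicity_result> RS = 6.734 (rhythmic)
#>   peak 0.615 at lag 24.0 h; 95% line 2/sqrt(480) = 0.0913
#>   estimated period: 24.0 h

bouts <- detect_sleep_bouts(sim$series, threshold = 5)
summarize_sleep(bouts, sim$schedule)
#> <sleep_summary> bee01, LD block (5 days)
#>   day:   336 min in 12 episodes (mean 27.6 min)
#>   night: 1056 min in 49 episodes (mean 21.7 min)

# treated vs control cohorts, rhythm strength in LD
ctrl  <- simulate_cohort(10, "control", seed = 1)
dosed <- simulate_cohort(10, "imidacloprid_10", seed = 2)
rs <- function(co) vapply(co, function(x) rhythmicity(x$series)$rs, 1)
two_sample_t(rs(ctrl), rs(dosed), labels = c("control", "imidacloprid_10"))
#> <group_comparison> student_t
#>   control          n =  10  mean =    6.941  sem = 0.170
#>   imidacloprid_10  n =  10  mean =    1.308  sem = 0.076
#>   t(18.0) = 30.230, p = 7.006e-17
```

The RS of 6.7 says the control subject's 24 h autocorrelation peak stands
6.7× above the white-noise band — strongly rhythmic — while the treated
cohort's mean RS falls near the 1.5 arrhythmicity cutoff; the t test reports
the group difference with pooled degrees of freedom n₁ + n₂ − 2.

`run_pipeline()` (or `inst/scripts/actirhythm.R` from a shell) orchestrates
the whole analysis for cohorts read from DAM-style or CSV monitor files or
simulated from presets, writing a per-subject results CSV, per-group
summaries, actogram matrices and a run log.

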