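# Versioned generator conventions for the treatment presets.
# Values encode effect DIRECTIONS (weaker rhythm, lower awake rate, more
# daytime sleep onsets, unchanged bout length), not measured quantities.
control:
  amplitude: 0.8
  base_rate: 2.0
  sleep_onset_rate_day: 0.004
  sleep_onset_rate_night: 0.02
  mean_bout_min: 20
  period_hours: 24
  acrophase_hours: 6
  n_days_ld: 5
  n_days_dd: 5
imidacloprid_1:
  amplitude: 0.5
  base_rate: 1.7
  sleep_onset_rate_day: 0.010
  sleep_onset_rate_night: 0.02
  mean_bout_min: 20
  period_hours: 24
  acrophase_hours: 6
  n_days_ld: 5
  n_days_dd: 5
imidacloprid_10:
  amplitude: 0.25
  base_rate: 1.4
  sleep_onset_rate_day: 0.020
  sleep_onset_rate_night: 0.02
  mean_bout_min: 20
  period_hours: 24
  acrophase_hours: 6
  n_days_ld: 5
  n_days_dd: 5
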