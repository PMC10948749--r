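# Cohort archetype presets for the synthetic CGM study generator.
# Glucose units mg/dL, times in hours of day, taus in minutes.
# The defaults are calibrated so that the full pipeline (15-min grid,
# day 2-14 window) reproduces the target cohort summary statistics of a
# 14-day healthy / pre-diabetic observational CGM study.
healthy:
  baseline_mean: 99.7
  baseline_latent: 6.0          # mg/dL shift per unit latent dysglycemia z
  baseline_sd_between: 7.0      # between-subject intercept SD
  baseline_sd_day: 5.0          # per-day baseline jitter SD
  drift_baseline_per_day: -0.35 # across-day improvement in baseline
  drift_amp_per_day: -0.012     # relative per-day change in meal amplitude
  circadian_amplitude: 6.0
  circadian_peak_hour: 16.0
  nocturnal_dip: 10.5           # extra nocturnal Gaussian dip depth
  nocturnal_dip_hour: 3.5
  nocturnal_dip_width: 2.5      # hours
  meal_times: [8.0, 13.0, 20.0]
  meal_time_jitter_sd: 0.5      # hours
  meal_amp_median: 33.0
  meal_amp_sdlog: 0.35
  meal_amp_latent: 0.12         # relative amplitude scaling per z
  meal_tau_min: 40.0            # time-to-peak / decay constant
  noise_sd: 7.0
  noise_rho: 0.8
  biomarkers:
    hba1c:    {mean: 5.0,  sd: 0.35, lo: 4.0, hi: 5.6,  loading: 0.12}
    ogtt_2h:  {mean: 112,  sd: 14,   lo: 75,  hi: 139,  loading: 5.0}
    fbg:      {mean: 90,   sd: 4.5,  lo: 79,  hi: 99,   loading: 1.5}
    insulin:  {meanlog: 1.95, sdlog: 0.35, loading: 0.12}
    hscrp:    {meanlog: 0.0,  sdlog: 0.55, loading: 0.10}
    cortisol: {mean: 11.5, sd: 3.0,  lo: 3,   hi: 25,   loading: 0.0}
    fbg_end_delta: {mean: -1.0, sd: 4.0}
  activity:
    steps: {mean: 8200, sd: 2200, loading: 350}
    hr:    {mean: 71,   sd: 5.5,  loading: 0.0}
    sleep: {mean: 425,  sd: 45,   loading: -8.0}
prediabetic:
  baseline_mean: 107.8
  baseline_latent: 8.5
  baseline_sd_between: 8.5
  baseline_sd_day: 5.5
  drift_baseline_per_day: -0.5
  drift_amp_per_day: -0.012
  circadian_amplitude: 9.0
  circadian_peak_hour: 16.0
  nocturnal_dip: 7.0
  nocturnal_dip_hour: 3.5
  nocturnal_dip_width: 2.5
  meal_times: [8.0, 13.0, 20.0]
  meal_time_jitter_sd: 0.5
  meal_amp_median: 29.0
  meal_amp_sdlog: 0.6
  meal_amp_latent: 0.2
  meal_tau_min: 45.0
  noise_sd: 9.0
  noise_rho: 0.8
  biomarkers:
    hba1c:    {mean: 6.0,  sd: 0.25, lo: 5.7, hi: 6.4,  loading: 0.15}
    ogtt_2h:  {mean: 165,  sd: 18,   lo: 140, hi: 199,  loading: 12.0}
    fbg:      {mean: 110,  sd: 6.5,  lo: 100, hi: 125,  loading: 2.5}
    insulin:  {meanlog: 2.45, sdlog: 0.35, loading: 0.32}
    hscrp:    {meanlog: 0.69, sdlog: 0.55, loading: 0.42}
    cortisol: {mean: 12.5, sd: 3.2,  lo: 3,   hi: 25,   loading: 0.0}
    fbg_end_delta: {mean: -1.5, sd: 4.5}
  activity:
    steps: {mean: 7600, sd: 2100, loading: 0.0}
    hr:    {mean: 74,   sd: 5.5,  loading: 1.2}
    sleep: {mean: 415,  sd: 48,   loading: -8.0}
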