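# kaps

Quantitative assessment of post-stroke elbow spasticity from robot-driven
passive stretch.

Spasticity — a velocity-dependent increase in resistance to passive muscle
stretch — is usually graded by hand on coarse ordinal scales (Modified
Ashworth, Modified Tardieu) with moderate reliability. The KAPS protocol
replaces the examiner's hand with a robotic exoskeleton that drives the
elbow through an 80° range (internal elbow angle 65–145°) at five nominal
durations (1500–600 ms), three trials each, recording joint angle and
angular velocity at 1 kHz. This package implements the complete analysis
for that protocol, plus a physics-based simulator so the pipeline can be
exercised and validated without hardware or patient data. It is intended
for movement-analysis researchers and for anyone building or evaluating
instrumented spasticity assessments.

Seven parameters are extracted per movement direction:

| # | Parameter | Definition |
|---|-----------|------------|
| 1 | Peak velocity | max |θ̇| during the stretch |
| 2 | Final angle | mean angle over the last 50 ms before the next movement |
| 3 | Creep | signed travel between 1 s post-stretch and the final angle (flexion: θ(post) − FA; extension: FA − θ(post)) |
| 4–6 | Between-arm differences | |ΔPV|, and signed ΔFA, ΔCreep (affected − reference arm) |
| 7 | Catch angle | excursion at which |v_aff − v_ref| first exceeds the control-derived velocity-difference threshold (50.1°/s default; positive extension, negative flexion) |

A normative model fitted on a healthy control cohort (age regression,
Box-Cox normalization with a Shapiro–Wilk gate, robust outlier screen,
sex-stratified 5th/95th-percentile cutoffs, 99th-percentile
velocity-difference threshold) converts a subject's parameters into
one-tailed impairment flags, z-scores, and failure counts over the 14
parameter × direction slots. Reliability tooling provides ICC(2,1)
(two-way random effects, absolute agreement) and tie-corrected Spearman
correlations with Bonferroni control (0.05/12 ≈ 0.004 for the standard
12-test family).

The simulator integrates a second-order limb driven by the robot's
published PD position controller (kp = 30 Nm/rad, kd = 2.5 Nm/(rad/s),
torque limit 13.2 Nm, half-cosine commanded trajectory, 0.26 Nm/deg hold
pull) with fixed-step RK4 at 1 kHz, and models spasticity as an
excursion-gated velocity-proportional resistance with exponential
post-stretch release, plus an optional one-sided contracture stiffness.
The methods vignette (`vignettes/kaps-methods.Rmd`) documents the model,
its assumptions, and every numerical choice.

## Worked example

Simulate a small control cohort and one spastic subject, fit norms, and
classify:

```r
library(kaps)

pro <- protocol_config(durations_ms = 600)      # fastest (most sensitive) stretch
controls <- simulate_cohort(96, protocol = pro, seed = 11)
model <- fit_normative_model(controls$params, controls$manifest)
print(model)
#> <kaps_model> 12 entries, 92 controls used ( 4 outliers removed )
#>   velocity-difference threshold: 2.17 deg/s ( fitted )
#>   extension  peak_velocity    tail=low  lambda=-3.00 strata=none cutoff(all)=206
#>   extension  final_angle      tail=low  lambda=-3.00 strata=sex  cutoff(all)=145
#>   extension  creep            tail=high nonparam   strata=none cutoff(all)=0.147
#>   extension  d_peak_velocity  tail=high lambda=-1.42 strata=none cutoff(all)=0.76
#>   ...

patient <- simulate_subject(
  limb_config(spastic_gain = 8, catch_onset_excursion = 35,
              contracture_limit = 120, contracture_stiffness = 1),
  limb_config(), protocol = pro, seed = 42, subject_id = "P1")
params <- extract_subject_parameters(
  patient, threshold = model$velocity_difference_threshold)
report <- assess_subject(params, model, age = 61, sex = "M")
print(report)
#> <kaps_report> P1: failed 10 of 14 parameters
#>   impaired: extension:peak_velocity, extension:final_angle,
#>   extension:d_peak_velocity, extension:d_final_angle, extension:d_creep,
#>   extension:catch_angle, flexion:peak_velocity, flexion:d_peak_velocity,
#>   flexion:d_creep, flexion:catch_angle
```

The printed model lists, per direction × parameter, the impaired tail, the
Box-Cox lambda (or a non-parametric flag), whether cutoffs are
sex-stratified, and the cutoff in original units; the report counts how
many of the 14 slots fall outside the control cutoffs (a detected catch
counts as a failure). A healthy subject assessed the same way typically
fails 0–2 slots.

Command-line equivalents of each step live in `inst/cli/kaps.R`
(`simulate`, `validate`, `extract`, `build-norms`, `classify`,
`reliability`, `correlate`).

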