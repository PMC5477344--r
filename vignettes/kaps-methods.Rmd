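---
title: "Quantifying elbow spasticity from robot-driven passive stretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying elbow spasticity from robot-driven passive stretch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaps)
```

## The measurement problem

Spasticity after stroke is a velocity-dependent increase in resistance to
passive muscle stretch. Clinical scales (the Modified Ashworth and Modified
Tardieu scales) grade it by hand on coarse ordinal levels with moderate
reliability. The KAPS approach instead drives the elbow through a fixed
80 degree range (internal elbow angle 65-145 degrees, extension increasing)
with a robotic exoskeleton at five nominal durations (1500 down to 600 ms),
records joint angle and velocity at 1 kHz, and reduces each assessment to
seven kinematic parameters per movement direction:

* **Peak velocity** - maximum angular speed during the stretch. Resistance
  lowers it.
* **Final angle** - resting angle at the end of the post-stretch hold; a
  proxy for passive range of motion (contracture).
* **Creep** - continued travel toward the target between 1 s post-stretch
  and the final angle; the operational "release" after a catch. Signed so
  that positive creep always means continued travel in the imposed
  direction.
* **Between-arm differences** in each of the three, using the less-affected
  (or dominant) arm as a within-subject reference.
* **Between-arm catch angle** - the excursion at which the affected arm's
  velocity first deviates from the reference arm's nominal profile by more
  than a control-derived threshold (positive in extension, negative in
  flexion).

Impairment is judged against a normative model built from a healthy control
cohort, parameter by parameter, with one-tailed percentile cutoffs.

## The trial simulator

No deposited recordings exist for this protocol, so the package carries a
physics-based generator that stands in for the robot and for subjects. A
single rigid limb with inertia $I$ obeys

$$ I\ddot\theta = \tau_{robot} + \tau_{passive} + \tau_{spastic} +
\tau_{contracture}. $$

During the commanded movement the robot applies the saturated PD +
feedforward law used by the real position controller, with the published
gains ($k_p$ = 30 Nm/rad, $k_d$ = 2.5 Nm/(rad/s), torque limited to
13.2 Nm) about a half-cosine commanded trajectory
$\theta_c(t) = \theta_s + (\theta_e-\theta_s)(1-\cos(\pi t/T))/2$ - the
simplest sine-based profile with zero endpoint velocities. After the
nominal movement end a weak proportional pull (0.26 Nm/deg) drives the arm
toward the target through the hold; if the target is still more than
1 degree away at the end of the hold, the achieved angle carries over as
the next movement's start angle, as on the real device. Note the published
control cohort reached higher peak velocities (about 306 deg/s in
extension) than the analytic peak of any simple 80-degree/600-ms sine
profile (about 209 deg/s); the exact commanded profile of the device is
not recoverable, so simulated velocities are internally consistent rather
than matched to the published means.

Pathology is modelled mechanistically with the simplest terms that
reproduce the catch, the reduced peak velocity, the range loss, and the
creep:

* **Spastic resistance**: a velocity-proportional torque
  $-g_s\,s(t)\,\dot\theta$ gated by excursion - it engages (latches) once
  the arm has travelled `catch_onset_excursion` degrees from the movement
  start, stays engaged through the movement, and decays exponentially with
  `release_time_constant` once the commanded movement ends. The decay is
  what produces measurable creep: the hold torque slowly wins against the
  fading resistance.
* **Contracture**: a one-sided stiffness beyond `contracture_limit`
  (degrees), resisting extension - tissue shortening shows up as an
  "earlier" final angle. Subjects with a contracture begin the protocol at
  the angle the positioning hold can actually reach (the hold-gain /
  contracture torque balance), mirroring the variable starting angles of
  real participants with restricted passive range.
* **Measurement noise**: additive Gaussian noise on the recorded angle
  only; velocity is recorded from the true state, as on the robot.

Integration is fixed-step RK4 at the 1 kHz output rate (compiled core), so
no interpolation is needed and trials are bit-reproducible given a seed. A
sanity bound on velocity converts numerical blow-up into an explicit
simulation-instability error.

The cohort generator draws per-subject mechanics lognormally (inertia
median 0.06 kg m$^2$, sdlog 0.15; passive damping median 0.10 Nm/(rad/s),
sdlog 0.25) with small independent per-arm multipliers (sdlog 0.03/0.05),
ages uniform on 19-81 years and a 43% male fraction, matching the
demographic envelope of the original control cohort. Optional effects map
age slopes or sex offsets onto limb properties, and an impaired fraction
receives spastic/contracture pathology from a severity preset. What the
generator does **not** emulate: antagonist co-contraction, trial-to-trial
neural variability, EMG, gravity (movements are in a supported horizontal
plane), or the soft passive elasticity that gives real healthy elbows a
spread of final angles. Passing tests therefore demonstrate that the
pipeline recovers what this model encodes, not that the model reproduces
every feature of patient data.

## Parameter extraction choices

Angle and velocity are filtered with a zero-phase (forward-backward)
2nd-order Butterworth low-pass at 10 Hz. Zero-phase filtering is chosen so
catch and velocity timing are not lag-shifted (a real-time implementation
would differ); the series is reflection-padded before filtering to keep
the ends transient-free. When a velocity channel is absent, velocity is
central-differenced from the filtered angle.

Analysis windows come from the command metadata, never from data-driven
onset detection - the robot's command clock is known in this protocol.
Final angle is the mean over the last 50 ms of the hold (noise-robust
rather than the literal last sample). The peak-velocity search extends
past the nominal movement end (capped at the controller timeout) when the
target was not reached, so slowly driven arms are credited with their true
maximum. Per-parameter values are averaged across the three same-duration
trials (configurable to the median); trials that never reached target
contribute their achieved trajectories unchanged. The catch detector
compares each affected trial against the time-aligned mean of the
reference-arm trials (trial-to-trial comparison is available), reports the
median excursion across trials with a crossing, and stays silent when no
trial crosses.

## The normative model

For each of the six modelled parameters per direction (catch is normed
through the velocity threshold instead):

1. **Age regression** (ordinary least squares on age; assumed linear).
   Subject values are age-adjusted by the control prediction relative to
   the control mean age, keeping original units.
2. **Box-Cox normalization** with maximum-likelihood lambda on a fine
   grid, after shifting positive (shift $= 1 - \min$) when needed. The
   normality gate is Shapiro-Wilk at alpha 0.01; parameters that fail stay
   non-parametric and use raw percentiles, with no z score.
3. **Outlier screen**: a control is dropped from *all* analyses when any
   normalizable parameter's robust z (median/MAD) exceeds 3.29. The screen
   deliberately skips non-normalizable parameters - 3.29 is a
   normal-theory threshold, and applying it to skewed raw values would
   trim exactly the tails the percentile cutoffs must estimate. More than
   25% exclusions aborts with an error (model misfit, not outliers).
4. **Sex and handedness tests** (Welch t on normalizable values, rank-sum
   otherwise, alpha 0.05). A sex effect switches that parameter to
   sex-stratified cutoffs (pooled fallback with a warning below 20 per
   stratum); a handedness effect is recorded.
5. **Cutoffs**: empirical 5th or 95th percentile per the parameter's
   impaired tail, computed in transformed space with the
   linear-interpolation order-statistic convention and back-transformed to
   original units. Single-limb parameters pool both control arms as
   observations, so cutoffs describe a single arm's distribution.
6. **Velocity-difference threshold**: the 99th percentile, over control
   participants (one value each, the larger of the two directions), of the
   peak of the between-arm $|$velocity difference$|$ trace.
   Two conventions matter here. First, the threshold is fitted from the
   peak of the difference *trace*, not from the difference of the two
   arms' peaks: since $\max_t|v_a - v_r| \ge |\max|v_a| - \max|v_r||$
   always, a 99th percentile of the smaller quantity could never keep
   healthy catch rates near 1% (the difference-of-peaks basis remains
   available behind `threshold_basis`). Second, this extreme percentile
   uses the $(n{+}1)p$ convention (type 6), whose expected healthy
   exceedance at $n \approx 100$ is the nominal 1%; the interpolation
   convention used for the 5th/95th cutoffs would give about 2% here.
   The threshold is part of the outcome-measure definitions and is fitted
   on the full control cohort *before* the outlier screen: excluded
   controls are precisely the high between-arm-asymmetry subjects, and
   dropping them first would truncate the tail the 99th percentile
   estimates. Without control data the packaged default of 50.1 deg/s is
   used and flagged.

Classification is one-tailed and strict: a value exactly at the cutoff is
normal. Z scores exist only for normalizable parameters and are oriented
so positive z points toward the impaired tail. A detected catch counts as
a failed parameter (its threshold is already the control 99th percentile),
giving up to 14 slots per subject; failure counts are reported with and
without the catch slot, and uncomputable parameters are listed and dropped
from the denominator.

One calibration fact worth stating explicitly: an interpolated empirical
95th percentile fitted on $n$ controls has expected held-out exceedance
$((n-1)p+1)/(n+1)$, about 5.9% at $n=96$ rather than 5.0%. The package's
calibration tests check flag rates against this order-statistic
expectation (averaged over independent fit/held-out replicates), because
no faithful implementation of the stated percentile definition can center
on exactly 5% at this cohort size.

## Reliability statistics

Between-rater agreement uses ICC(2,1) - two-way random effects, single
measure, absolute agreement - computed from the two-way ANOVA mean
squares, so a systematic rater offset lowers the estimate. Validity
against clinical scores uses tie-corrected Spearman correlation (Pearson
on midranks) with Bonferroni control; with the published family of 12
tests the corrected level is 0.05/12, printed as 0.004. P values are
exact by full permutation enumeration for n of 7 or fewer and use the t
approximation above that (full enumeration beyond that size is not a
desk-scale computation; the composition of the original 12-test family is
an explicit argument since it is not fully enumerated in the source
protocol).

## Numerical and testing choices

Problem sizes in the test and acceptance runs are chosen to finish on one
CPU in minutes while keeping the statistics meaningful: cohort-level
checks fit on 96 simulated controls (the original cohort size) restricted
to the 600 ms condition - the duration the protocol found most
discriminative - and classify 500 held-out healthy subjects per
replicate, averaged over four fit/held-out replicates; discrimination
uses 200 held-out controls and 40 severe subjects. Box-Cox recovery
fixtures (lognormal sdlog 1.0; Normal(10,4) truncated at zero) are chosen
so lambda is statistically identifiable at n = 96, and the recovered
lambda is the median over five replicate samples. The catch-recovery grid
uses a spastic gain of 10 Nm/(rad/s) - strong enough to stall the stretch
against the torque-limited controller - over onset excursions of 20-60
degrees.

Known limitations: the simulator's healthy final-angle spread is much
narrower than real passive-range variation (no end-range elasticity);
simulated peak velocities are not tuned to the published control means
(commanded-profile ambiguity above); the spastic mechanism is a
phenomenological gate, not a reflex model; and sex/age effects exist in
simulation only when explicitly injected, so the sex-stratification
machinery is exercised by injection rather than emergent differences.
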