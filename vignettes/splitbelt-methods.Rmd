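---
title: "Split-belt adaptation analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-belt adaptation analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitbelt)
```

## The problem this package addresses

Split-belt treadmill walking — the two belts driven at different speeds,
here in a 2:1 fast:slow ratio with the paretic leg on the slow belt — is a
motor-adaptation paradigm used to probe and rehabilitate gait asymmetry
after stroke. A session consists of a Baseline epoch (tied belts at the
subject's mid speed, at least 50 strides), an Adaptation epoch (split
belts, at least 300 strides), and a Post-Adaptation epoch (tied belts
again, at least 10 strides). The analysis reduces raw motion-capture and
force-plate recordings to stride-by-stride gait parameters, collapses them
into epoch outcome measures, and runs a group statistical battery. This
package implements that reduction end to end, together with a synthetic
trial generator carrying known stride-level truth, so every stage can be
validated quantitatively without access to recorded data.

## Signal model and processing chain

**Coordinate frames.** All spatial parameters are defined in the
treadmill-surface frame: +x uphill along the belts, +y mediolateral, +z
orthogonal to the surface; positions in mm, forces in N, time in s. On an
inclined treadmill the capture system reports lab-frame coordinates;
`rotate_to_surface()` applies the rotation about the mediolateral axis (by
the session slope, 5 or 8.5 degrees in the reference protocol) to both
marker positions and force vectors. The transform is an isometry and its
round trip is tested to numerical precision.

**Belt speeds.** The slow belt runs at 66.6% and the fast belt at 133.3%
of the subject's mid speed, each rounded half away from zero to 0.01 m/s
(treadmill resolution). This yields a 2:1 ratio and keeps
(slow + fast)/2 equal to the mid speed, so the average belt speed is the
same in every epoch. Half-away-from-zero was chosen because a rounding
convention has to be fixed to reproduce printed protocol tables; it is the
convention consistent with the reference cohort's speed table except for
two entries whose printed mid speeds are themselves rounded too coarsely
to decide (the derived value differs by exactly 0.01 m/s there).

**Gait events.** A heel strike is the first sample at or above threshold
of a sufficiently long loaded interval of the normal ground-reaction
force; stance end is the first sample back below threshold of a
sufficiently long unloaded interval. Two threshold modes exist: the
real-time emulation (30 N on raw force, used by treadmill operators to
count strides) and the offline rule (10 N on force median-filtered with a
5 ms window), which is the analysis default. Loaded/unloaded intervals
shorter than 100 ms are debounced (merged); these debounce windows are far
below physiological stance and swing durations, so they only suppress
sensor chatter. The detector is verified against a literal brute-force
scan oracle on random traces.

**Strides.** A stride is the interval between two consecutive heel
strikes of the same leg; the paretic leg is the reference for stride
counting. A well-formed stride contains exactly one contralateral heel
strike; malformed intervals are dropped and counted. Strides spanning a
belt-speed transition are dropped so no stride mixes conditions, and
resting breaks (zero force) produce no events, hence no strides.

**Spatial parameters.** Step length (SL) is the anterior-posterior
distance between the ankle markers at the leading leg's heel strike. Step
length asymmetry is

$$\mathrm{SLA} = \frac{SL_{np} - SL_p}{SL_{np} + SL_p},$$

unitless, zero when symmetric, positive when the non-paretic step is
longer. Each step decomposes about the hips (mean of the two greater
trochanter x positions) into the leading position alpha (positive ahead
of the body) and the trailing position X (negative behind it), with
alpha_lead − X_trail = SL identically — an invariant asserted on every
extracted stride. Force-derived event times (1000 Hz) are mapped to the
nearest kinematic frame (100 Hz, at most 5 ms of discretisation, well
below gait scales). Marker occlusion gaps are filled by an interpolating
quintic polynomial through the three nearest valid frames on each side;
an interpolating (smoothing parameter zero) dialect is assumed because
nothing harder is recoverable from the processing description this
mirrors. Gaps longer than the configured maximum and edge gaps stay
masked, and strides touching masked frames are excluded listwise from the
affected parameters only.

**Kinetic parameters.** The anterior-posterior force is low-pass filtered
(4th-order Butterworth, 20 Hz cutoff, forward-backward for zero phase
lag, with odd-reflection padding to suppress end transients) and divided
by body mass. Peak propulsion is the maximum of that signal between peak
braking and stance end: anchoring the search at the braking minimum is a
parameter-free way to exclude the brief positive transient that can
follow heel strike. Stances whose AP force never goes negative fall back
to the second-half maximum and are flagged atypical. Slope-specific
gravity biases are deliberately not removed at this stage; all
between-condition comparisons are made on epoch differences downstream.

## Epoch outcome measures

For every parameter and session, five measures: **Baseline** (mean of the
last 40 strides of the mid-speed baseline), **Late Adaptation** (mean of
the last 40 adaptation strides minus Baseline), **After-Effects** (mean
of the first 5 post-adaptation strides minus Baseline), **ΔAdapt** (late
minus early adaptation) and **ΔPost** (Baseline minus early
post-adaptation, Baseline standing in for late post-adaptation because
post epochs are too short to extinguish after-effects — a stated
limitation of the design). ΔPost = −After-Effects follows algebraically
and is asserted numerically on every run. The literal difference formulas
are stored; any increase-in-magnitude sign convention for reporting is
left to presentation code, because baking it into stored values would
make it unverifiable for parameters with negative baselines (X). Missing
strides extend the averaging window rather than shrinking it; epochs with
too few valid strides raise an error naming the epoch. Time courses are
summarised in 5-stride bins with trailing partial bins flagged.

## The synthetic generator

The generator is first-class, tested code, not a fixture. Its stride
layer draws, per parameter, a single-exponential adaptation curve
p(s) = p_ss + (p0 − p_ss)·exp(−s/τ) within Adaptation, an exponential
washout baseline + a0·exp(−s/τ_w) within Post-Adaptation, and stationary
baselines, plus i.i.d. Gaussian stride noise. A single exponential is the
simplest curve consistent with observed split-belt time courses; a double
exponential can be emulated by summing runs but is not needed to exercise
the analysis. Defaults: τ = 45 strides, τ_w = 12 strides; leading
position alpha ≈ 252·v mm and trailing position X ≈ −348·v mm at belt
speed v (so step times stay near 0.6 s across the cohort's speed range),
inclination shifts X by −150·sin(slope) mm and adds the gravitational
g·sin(slope) N/kg to propulsion, and the paretic leg carries fixed
deficit factors (0.92 on alpha, 0.75 on propulsion). Adaptation starts
with a 1.6-fold overshoot past the speed-specific steady state and
post-adaptation retains half the adaptation shift, with the X
after-effect swapped between legs (ipsilateral alpha, contralateral X
retention), mirroring the retention structure seen in split-belt studies.
Stride-to-stride noise defaults to 8 mm for positions and 0.06 N/kg for
propulsion; sensor noise to 0.5 mm (markers) and 1 N (force channels).

The signal layer schedules heel strikes on the 100 Hz kinematic grid and
emits, per stance: a two-Gaussian normal-force waveform (peaks near 25%
and 75% of stance, 1.1 body weight) that crosses the 30 N threshold at
the scheduled strike; a biphasic braking-then-propulsion AP waveform
whose propulsion lobe maximum encodes the stride's true peak, plus an
optional early-stance positive transient that exercises the exclusion
rule; ankle markers that land at hip + alpha and travel backward at belt
speed until the contralateral strike at hip + X; and hip markers
oscillating smoothly about a fixed point. Everything is built in the
surface frame and rotated into the lab frame by the slope, so the
analysis must undo the rotation. Because strikes are snapped to the
kinematic grid, the generator records the *attained* alpha/X at the
snapped frames as truth; signals and truth tables are therefore exactly
consistent, and noise-free full-loop recovery is limited only by
filtering (observed: position errors below 1e-9 mm, propulsion within
0.002%).

What the generator does not emulate: musculoskeletal dynamics, realistic
GRF waveform shape variability, cross-stepping onto the wrong belt,
marker occlusions during fast motion, handrail loading, or drift in the
capture volume. Passing tests therefore demonstrate that the *analysis*
is correct and internally consistent under the stated signal model — not
that it is robust to every artefact of real motion-capture data.

## Statistical battery

Paired t-tests with the paired Cohen's d_z = mean(diff)/sd(diff) (the
averaged-SD variant d_av is available as an option); one-sample t-tests
with Bonferroni correction (p multiplied by the number of comparisons,
capped at 1). Repeated-measures ANOVA uses the univariate
sums-of-squares decomposition with subjects as a random blocking factor:
each within-subject effect is tested against its effect-by-subject
interaction mean square, and in mixed designs the between factor is
tested against the between-unit residual; when the same subjects appear
in both levels of the "between" factor (as with the ΔAdapt/ΔPost epoch
factor) the blocking unit is the subject-by-epoch combination, making
epoch a between-unit factor by construction. Effect sizes are classical
eta squared, SS_effect/SS_total over the full decomposition (subject
stratum included). Effects with zero sum of squares report F = 0, p = 1
rather than 0/0.

Normality is assessed with the Lilliefors test; the p-value is Monte
Carlo (Gaussian null samples of the same n with re-estimated parameters,
seedable, with the (1+k)/(R+1) correction) rather than a table lookup, so
it is exact for any n and reproducible. The analysis logs the gate
decision but always reports the parametric tests; it never auto-switches
to nonparametric alternatives. Leg-orientation predictions use the
through-origin model |y| = a·|z| — absolute values prevent the
positive-alpha/negative-X clustering from linearising the fit trivially —
with se and CI on n − 1 degrees of freedom and the *uncentered* R²
(1 − RSS/Σy²), which is the definition under which R² can exceed the
squared Pearson r reported alongside it; the centered Pearson r is given
as the effect size.

## Numerical choices and degenerate inputs

Event debounce 100 ms/100 ms; median window 5 ms (5 samples at 1000 Hz,
centered, shrinking at the edges); Butterworth order 4, zero-phase, with
reflection padding of 20·fs/cutoff samples; quintic fill uses 3 + 3
neighbouring frames with a centered/scaled Vandermonde solve for
conditioning. Zero-variance samples, all-zero predictors, epochs with too
few valid strides, non-positive time constants, and configs violating the
speed rule all raise typed errors (`splitbelt_degenerate_data`,
`splitbelt_singular_fit`, `splitbelt_epoch_length_error`,
`splitbelt_invalid_parameter`, `splitbelt_schema_error`). Re-applying
baseline-bias removal is refused via a table attribute, since double
subtraction is silent and wrong.

## Problem sizes used by the test and acceptance runs

The shipped tests and the acceptance script exercise the full pipeline at
50 baseline / 150–200 adaptation / 40–60 post-adaptation strides per
session (12 subjects, flat and incline), and the noisy-recovery harness
at 20 seeded replicates of single sessions. These sizes are the package's
own demonstration scale: noise-free recovery accuracy does not depend on
epoch length, and the windowed outcome measures only require 40-stride
tails and 5-stride heads, which these plans satisfy with margin. The
generator's defaults (600 adaptation / 300 post strides) match the
reference protocol scale and are used when callers do not override the
epoch plan.

## Known limitations

Per-belt force attribution assumes each foot stays on its own belt;
cross-stepping is not detected. The ΔPost measure inherits the
Baseline-as-proxy limitation described above. The regression layer pools
legs and sessions as the study design dictates, but with synthetic truth
the pooled points are not independent in the way real subjects are, so
its p-values describe the synthetic cohort only. Cohort-level effect
sizes from the reference study are not reproducible without the original
recordings and are deliberately out of scope.

## A minimal session

```{r example, eval = FALSE}
cfg <- protocol_config("S1", mass_kg = 72, paretic_side = "right",
                       slope_deg = 0, mid_speed = 0.75)
res <- run_session(cfg, seed = 1, noise = "realistic")
res$outcomes
study <- run_study(seed = 1, n_subjects = 12)
study_stats(study)
```
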