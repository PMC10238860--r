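---
title: "Pulsatile hemodynamics with pulsewave: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsatile hemodynamics with pulsewave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## What the package computes

`pulsewave` analyses continuous aortic pressure (and optionally flow)
recordings with three complementary methods:

* **Pulse wave analysis (PWA)** extracts morphologic landmarks — the early
  systolic shoulder P1, the late systolic peak P2, and the dicrotic notch
  DN — from an ensemble-averaged, normalized pressure waveform, using the
  sign structure of its first through fifth finite-difference derivatives.
  From the landmarks mapped back onto each contributing beat it computes
  augmented pressure (Ap, mmHg), ejection duration (ED, ms) and its split
  into the round-trip reflection time (Tr, foot to P1) and the reflected
  wave's systolic duration (SDR, P1 to DN), and the pressure–time areas:
  wasted effort E~w~ (the systolic area of the reflected wave above the
  inflection point), pressure systolic area PSA (area above diastolic
  pressure minus E~w~), the total systolic and diastolic pressure–time
  integrals SPTI and DPTI, and ΔSPTI = SPTI − PSA − E~w~. By construction
  `ED = Tr + SDR` and `SPTI = ΔSPTI + PSA + Ew` hold exactly.

* **Wave separation analysis (WSA)** estimates the proximal aortic
  characteristic impedance Zc as the least-squares slope of the
  early-systolic pressure–flow relationship (flow onset to 50% of peak
  flow, before reflections return), then decomposes diastole-zeroed
  pressure into forward and backward waves,
  `Pf = (P + Q·Zc)/2`, `Pb = (P − Q·Zc)/2`, so that `Pf + Pb = P` and
  `Pf − Pb = Q·Zc` at every sample. Reflection magnitude is
  `RM = Pb/Pf` amplitude ratio; QZc is the systolic time-integral of
  `Q·Zc` (mmHg·ms); wasted pressure effort is the systolic integral of
  `max(P − Q·Zc, 0)`, the reflection-attributable extra load, with the
  clamp at zero because a negative "wasted" load is physically
  meaningless.

* **Wave power analysis (WPA)** forms per-sample differences dP and dQ on
  a canonical 500 Hz grid and classifies the power `dΠ = dP·dQ`
  (converted to µW by 133.322 µW per mmHg·mL/s) by sign pattern:
  forward compression (+dΠ, +dP, +dQ, early systole), forward expansion
  (+dΠ, −dP, −dQ, late systole), and backward compression
  (−dΠ, +dP, −dQ, mid systole). An absent backward wave is a normal
  finding. The FCW/FEW height ratio is dimensionless and invariant to any
  rescaling of the flow units, which is what licenses computing it from
  uncalibrated synthetic flow.

* **Pressure-only synthetic flow** builds an uncalibrated flow estimate
  from a single pressure beat: flow is concordant with diastole-zeroed
  pressure up to the inflection point; from there a quasi-linear reflected
  ramp (0 at the inflection, rising to the notch pressure at DN, held
  through the notch trough) is subtracted, forcing zero flow at end
  ejection and reproducing the brief early-diastolic reversal; flow is
  zero after the first post-notch diastolic pressure maximum. Only
  flow-scale-invariant indices are reported from synthetic flow (Pf/Pb
  amplitudes, RM, QZc, wasted effort and ratio, FCW/FEW ratio); absolute
  Zc and absolute wave-power heights are deliberately suppressed.

## The paired-waveform simulator

Because no canine telemetry recordings are available to ship, the package
carries a tube-load simulator with exact ground truth
(`sim_params()`, `simulate_beat()`, `simulate_recording()`). One beat is
built from a forward ejection wave and a delayed, attenuated reflection:

* The forward flow lobe is `q0(t) = A·(u·e^(1−u))^a` with `u = t/tp`,
  a smooth (infinitely differentiable) asymmetric pulse peaking at
  `tp = frac_tp·ED`. The exponent `a` (`shape_a`) controls the sigmoidal
  onset and the rise/fall asymmetry: small `a` gives the rapid upstroke of
  a vigorously contracting ventricle, large `a` the slower, more
  symmetric lobe of a failing one. A smooth lobe matters here: piecewise
  half-sine constructions carry curvature discontinuities that dominate
  fourth and fifth derivatives and defeat the landmark logic the
  simulator exists to exercise.
* Forward pressure is `pf = Zc·q0` through ejection, then decays
  exponentially with time constant `tau_decay_ms` from its end-ejection
  value. An incisura — a raised-sine negative flow lobe spanning
  `inc_width_ms` (default 30 ms) with depth `inc_frac` (default 15% of
  peak flow) and its mirrored pressure deflection — is folded into the
  forward wave at end ejection, which guarantees a detectable dicrotic
  notch and a post-notch diastolic rebound while preserving the
  conservation identities exactly. (A 20 ms/10% lobe proved too shallow:
  once the decaying reflected wave is superimposed, the rebound drops
  below 0.1 mmHg and the pressure-only synthesis has no anchor.)
* The backward wave is a pure delayed, scaled copy,
  `pb(t) = γ·pf(t − τ)`, so the generative reflection magnitude is
  exactly `γ`. Pressure is `DBP + pf + pb + noise` and flow
  `(pf − pb)/Zc + noise`; the flow amplitude is rescaled so the
  positive-flow integral equals the requested stroke volume to within
  numerical quadrature error.

This model is deliberately stylized. It reproduces the features the
analysis chain keys on — reflection timing and magnitude, notch
morphology, exponential diastolic decay, realistic pressures (≈70–130
mmHg) at canine heart rates (60–130 bpm) — but not secondary properties of
real aortic flow: the mid-systolic flow profile visibly carries the
subtracted reflection, diastolic forward flow is not exactly zero, beats
are concatenated without carry-over of the previous beat's tail (a ≲2 mmHg
step at each onset), and baseline wander, respiration and ectopy are
absent. Passing tests on simulated data therefore demonstrate algorithmic
correctness against known ground truth, not field performance on telemetry
recordings.

### Heart-failure progression presets

`hf_preset()` encodes three study arms of a rapid-ventricular-pacing
cardiomyopathy progression. Heart rate, stroke volume and the reflection
coefficient are pinned to the reported means (86.5/99.1/120.9 bpm,
41.2/28.0/20.8 mL, γ = 0.48/0.39/0.38), and Zc is held at
1.89 mmHg·min/L = 0.1134 mmHg·s/mL in all arms (pacing leaves aortic Zc
unchanged; the unit conversion assumes the reported impedance refers to
flow in L/min). The remaining knobs are not reported for the animals and
were fixed once on physiologic grounds:

| parameter | baseline | week 1 | month 1 | rationale |
|---|---|---|---|---|
| ED (ms) | 230 | 210 | 180 | shortens with heart rate |
| τ (ms) | 70 | 90 | 85–90 | slower wave speed at lower pressure |
| frac_tp | 0.35 | 0.44 | 0.50 | later peak flow as contractility falls |
| shape_a | 2 | 4 | 5 | slower upstroke (+dP/dt falls ~60%) |
| DBP (mmHg) | 72 | 60 | 58 | mean pressure falls ~20 mmHg |
| τ~decay~ (ms) | 350 | 320 | 300 | stiffer-run-off failing circulation |
| noise | 0.5 mmHg / 2 mL/s | — | — | telemetry-grade measurement noise |

With these settings a 40-beat session reproduces the qualitative
progression signature — monotone declines in stroke volume, PSA, Pf and
Pb amplitudes, QZc, wasted effort and the FCW/FEW ratio, with Zc constant
to within a few percent — and session means land close to the reported
ranges (e.g. baseline PSA ≈ 6.9 mmHg·s, Pf ≈ 43 mmHg, Pb ≈ 22 mmHg,
RM ≈ 0.50).

## Numerical and algorithmic choices

**Filtering.** Pressure is smoothed with a Savitzky–Golay filter (window
23 samples, order 2) followed by a zero-phase Butterworth low-pass at
10 Hz (applied forward–backward over a reflection-padded series). The
heavy low-pass is required for stable fourth/fifth derivatives but has two
side effects the pipeline corrects for: (i) it flattens the early-systolic
upstroke, biasing the pressure–flow slope (Zc) low by ~30%, so WSA, WPA
and flow synthesis run on Savitzky–Golay-only smoothed signals, with flow
given the same linear smoother (unequal filtering of P and Q would bias
the slope even on clean data); and (ii) it drags the smoothed diastolic
nadir into the shallow decay limb, so the beat foot is refined from the
nadir to the local curvature maximum, restoring ±1-sample onset accuracy
on clean beats with a sharp foot. For lobes with a very soft (zero-slope)
onset the refined foot can still sit a few samples late; this is a
property of the foot definition, not of the detector.

**Beat detection.** Systolic peak candidates are local maxima above an
amplitude midline; the refractory interval (0.25 of the beat period) uses
an autocorrelation period estimate because strongly augmented beats carry
two systolic humps and inter-candidate spacing is then bimodal. Candidate
peaks deviating more than 30% from the trailing 10-peak moving average of
peak amplitudes are rejected as artifacts (the window length follows the
study design; the threshold is this package's choice, exposed in
`pw_config()`).

**Ensemble averaging.** Groups of eight consecutive beats are resampled
to a common 500-point grid, min–max normalized, and averaged;
"normalization in amplitude and notch duration" is realized as full-beat
time normalization because a notch-anchored piecewise warp would need the
notch before PWA has found it. Per-member time and amplitude scales are
retained so landmarks found on the mean map back to each beat
(`landmark_to_member()`). Incomplete trailing groups are discarded.

**Derivative chain.** Successive central differences with light
Savitzky–Golay re-smoothing (window 11, order 3) between orders; without
the re-smoothing, fifth differences of a 500-sample waveform are
numerically unusable. Only sign structure matters downstream, so the grid
scale is immaterial.

**Landmark logic.** The branch is chosen by the sign of the fifth
derivative at peak pressure: negative selects the positive-augmentation
branch (P2 at the maximum, P1 at a fourth-derivative down-crossing after
the steepest upstroke), positive (or exactly zero) the negative branch
(P1 at the maximum, P2 at the first up-crossing after it). Two
robustness refinements were needed in practice. First, the ordinal
position of the P1 crossing ("second after the maximum of the first
derivative") is not invariant: when the reflection arrives close to the
forward peak, the upstroke's own curvature reversal and the shoulder
merge into a single crossing, so the locator accepts the second crossing,
then the first, then falls back to the negative branch, requiring a
consistent ordering (P1 < P2 < DN) at each step. Second, the dicrotic
notch — the first third-derivative down-crossing after the pressure
maximum — is constrained to the physiologic ejection window (27–55% of
the cycle at 60–130 bpm) and to follow every systolic landmark, because a
reflected wave still rising after the peak produces earlier, spurious
curvature reversals. Beats with no consistent landmark set are excluded
and counted, never imputed.

**Wasted effort in the negative-augmentation branch.** The area above
"P1 or P2 as determined by waveform augmentation" is anchored at P2 (the
inflection) for negative augmentation; when no P2 crossing exists the
beat has no discernible reflected shoulder and E~w~ is zero.

**Zc windows.** The default slope window runs from flow onset (last
crossing of 5% of peak flow) to 50% of peak flow; a fixed-duration
(60 ms) alternative is available via `pw_config(zc_mode = "fixed_ms")`.
Per-beat Zc estimates are averaged per session rather than fitting one
loop per ensemble.

**Synthetic-flow anchors.** The notch trough is searched within 25 ms
after DN and the diastolic rebound within 60 ms after the trough, on a
lightly re-smoothed curve; wide or prominence-based searches fail on the
decaying reflected tail, which can sink below the trough later in
diastole. Beats with no rebound above 0.1% of pulse height are skipped.
For negative-augmentation beats the ramp anchors at P2.

**Wave-power windows.** FCW is sought between foot and peak pressure,
FEW between peak pressure and DN plus a 20 ms margin, BCW anywhere in
systole; signals are resampled to 500 Hz before differencing so µW
magnitudes are comparable across sampling rates.

## Agreement statistics

`bland_altman()` reports the mean difference and 95% limits of agreement
(bias ± 1.96·SD, sample SD) between paired per-beat indices from measured
and synthetic flow; `spearman_rho()` is the Pearson correlation of
average ranks. In `analyze_recording()` the agreement block is present
only when both flow sources were computed. Agreement between the two flow
sources degrades monotonically with pressure noise, which the test suite
checks over a seeded noise sweep (0.5, 2, 6 mmHg).

## Problem sizes and reproducibility

The shipped tests and the acceptance analysis use 8–40-beat sessions,
5-point impedance and 7-point reflection grids, and 50 seeded replicates
for the noisy reflection-magnitude recovery — sizes at which every
property is already stable while a full run stays in the tens of seconds.
All randomness flows through explicit integer seeds; `simulate_recording()`
is bitwise reproducible for a fixed seed, and `analyze_recording()` is
deterministic given its inputs.

## Known limitations

* The simulator's flow waveform carries the subtracted reflection
  visibly; shape-concordance of synthetic flow with "measured" flow is
  therefore highest when the reflection arrives late in systole and lower
  than on real canine recordings otherwise.
* Landmark logic was designed against real arterial morphologies; on
  waveform families with soft feet or near-degenerate shoulders (weak
  reflection under positive-augmentation classification) single beats can
  be excluded. Exclusion counts are reported per session.
* Absolute wave-power magnitudes depend on the generator's steep synthetic
  slopes and are not comparable to published µW values; directions and
  ratios are.
* Repeated-measures ANOVA with multiple-comparison correction, used in
  the original study design for group inference, is routine statistics
  and intentionally out of scope; the package stops at per-session
  indices and method-agreement statistics.
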