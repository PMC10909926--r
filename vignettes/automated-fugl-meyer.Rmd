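---
title: "Automated Fugl-Meyer scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated Fugl-Meyer scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autofma)
```

## The problem

The upper-extremity Fugl-Meyer assessment (FMA-UE) grades post-stroke
motor function over 33 items, each scored 0 (cannot perform), 1 (partial)
or 2 (full), for a clinical maximum of 66. Manual administration is slow
and rater-dependent. `autofma` scores the 30 items that can be measured
with a markerless camera skeleton (Kinect-style body joints plus 21-point
hand landmarks) and a 16x16 thin-film pressure grid for the five grasp
items; the two reflex items, which need a reflex hammer, are out of scope.

The central design idea is *bilateral referencing*: the healthy limb is
recorded performing the same motions and every feature enters scoring as
an affected/healthy ratio (or a deviation normalised by the healthy side).
This removes most inter-subject variability — each patient is their own
control — at the cost of assuming the contralateral limb is functionally
intact.

## Pipeline

1. **Conditioning.** Every position channel is filtered with a zero-phase
   (forward-backward) fourth-order Butterworth low-pass at 12 Hz. Zero
   phase matters because the deviation feature compares the two sides
   point by point; a causal filter's lag would bias it. Filtering is
   applied to *positions*, not derived angles: angles are bounded
   nonlinear functions of position, and filtering them would distort
   near range limits. The sampling rate is carried in the recording
   (`fs > 24` Hz so the cut-off stays below Nyquist).
2. **Kinematics.** A thorax frame is built from the spine-chest-to-neck
   axis with the inter-hip line as the lateral reference (the pelvis is
   rigid with the trunk; using the shoulders would let scapular motion —
   the very thing two items measure — rotate the reference frame; the
   shoulder line is the fallback when hips are untracked); a humerus
   frame comes from the
   elbow-to-shoulder axis with the forearm direction as the floating
   anterior reference (the published construction names the axes but not
   how to obtain the anterior axis from camera joints; the forearm-based
   choice keeps axial rotation observable whenever the elbow is flexed,
   with a thorax-referenced fallback for a straight arm). Shoulder angles
   come from the ISB-recommended Y-X-Y decomposition (plane of elevation,
   elevation, axial rotation), mapped to clinical labels as
   `flexion = elevation * sin(plane)`, `abduction = elevation * cos(plane)`.
   At the `elevation = 0` singularity the whole rotation is assigned
   deterministically to the plane angle. Elbow flexion is the interior
   angle complement (0 = fully extended, matching reported elbow traces of
   0-2 degrees for a straightened arm). Forearm pronation is the rotation
   of the palm normal about the forearm axis measured against the elbow
   flexion-plane normal and referenced to the clip's first sample — the
   protocol tracks rotation *during* a motion, not an absolute anatomical
   zero. Finger bends use the published landmark-pair vectors with the
   2-D arccos expression generalised to 3-D.
3. **Features.** Per angle trace: range of motion (max - min), mean
   absolute angular velocity, and the RMS deviation between the resampled
   affected and healthy traces. Reach tasks produce completion ratios
   (hand-to-hip, fingertip-to-nose), fingertip peak speed, mean speed and
   mean acceleration magnitude. Grasp items use the per-cell maximum force
   grid, thresholded at 0.1 N (the grid's detection floor; configurable)
   and summed.
4. **Fuzzy scoring.** Each sub-motion's ratio vector feeds a Mamdani
   inference system with three trapezoidal input sets (low / medium /
   high: `[-0.4,-0.1,0.1,0.4]`, `[0.1,0.4,0.6,0.9]`, `[0.6,0.9,1.1,1.4]`)
   and three triangular output sets on `[0, 2]` (`[0,0,1]`, `[0,1,2]`,
   `[1,2,2]`), min implication, max aggregation and centroid
   defuzzification on a 2001-point grid. Crisp scores are discretised to
   the nearest integer (half-points round down, the conservative choice).
   Items composed of several sub-motions combine their integer sub-scores
   with a weakest-link rule: any 0 forces 0, all 2 gives 2, otherwise 1.
5. **Report.** Total = sum of the 30 item scores (0-60); severity classes
   use the published clinical cuts (below 32 severe, 32-57 moderate,
   58-66 mild). Those cuts refer to the 66-point scale while the
   automated total spans 60; by default the raw total is classified and
   the caveat is recorded in the report, with an optional
   `rescale66 = TRUE` to classify `total * 66/60`.

## Design choices in the open points

* **Rule base.** The published rule table is not machine-readable, but the
  accompanying text states the monotone directions (higher ROM/velocity
  ratios better, larger deviation worse). The default base is therefore
  constructed, not transcribed: each input label maps to an oriented level
  (inverted for "worse when larger" inputs) and the output label is the
  minimum of the oriented levels. This is the conservative clinical
  reading — the weakest aspect of a movement limits its grade — and it
  makes the inference monotone by construction. The base is plain data in
  the FIS specification and can be replaced wholesale from a JSON config.
* **Input saturation.** Ratios are clipped onto the support of the outer
  membership plateaus (`[-0.1, 1.1]` intersected with the `[0, 1.4]`
  universe). Clipping exactly to 1.4 — the upper trapezoid's outer knot —
  would land in a sliver where *no* membership function fires; an
  affected side that outperforms the healthy side should saturate at full
  "high" membership instead.
* **Deviation normalisation.** The RMS deviation is in degrees while its
  membership functions live on a unit-like domain, so it is divided by
  the healthy ROM (the natural per-item scale) and clipped at 1.4.
* **Direction of the reach ratios.** The hand-to-hip ratio and the
  fingertip-to-nose ratio both *decrease* toward 0 as the target is
  reached, while scoring needs "larger is better" ratios whose value is 1
  when the sides are equivalent. Both are therefore converted to
  completion values (`1 - min ratio`) before forming the
  affected/healthy quotient; this also restores the stated monotonicity
  ("the greater the ratio, the better") that the raw definition
  contradicts. The same parity logic applies to features whose ideal
  value is equality rather than magnitude (the dysmetria shoulder-distance
  ratio and the tremor acceleration ratio use `1 - |ratio - 1|`).
* **Failure to initiate.** If the affected fingertip moves less than 2 cm
  in the finger-nose task, its speed and acceleration features are zero
  rather than tracker-noise derivatives — differentiation otherwise
  manufactures a velocity floor out of jitter on a limb that never moved.
* **Wrist stability items.** The 15-degree dorsiflexion mentioned for the
  wrist-stability items is treated as a feature (the maximum dorsiflexion
  reached, via ROM/velocity/deviation ratios), not as a hard gate.

## The synthetic generator

No public recordings exist for this protocol, so the package ships a
first-class generator of paired healthy/affected sessions:

* Healthy motion: minimum-jerk angle profiles (1 s movement, then hold,
  in 5 s clips at 30 Hz) on a seated skeleton with fixed segment lengths;
  cyclic motions (forearm rotation, repeated wrist flexion) are
  sinusoidal. Hand landmarks come from a geometric template whose distal
  segments are rotated so the measured bend angle equals the commanded
  curl exactly.
* Impairment: the affected side scales every excursion by `rom_scale`,
  stretches its movement phase by `1/velocity_scale`, adds a 6 Hz tremor
  sinusoid, scales its force blobs by `force_scale` and can lose
  individual fingers' contact blobs entirely.
* Jitter: band-limited (1 Hz low-passed) Gaussian position noise,
  0.05 mm by default, on every joint and landmark of both sides.
  Model-based markerless trackers produce slowly wandering estimates
  rather than per-frame white noise (white jitter would noise-floor every
  velocity feature, incompatible with such features being usable at all on
  this hardware); the amplitude is the residual after tracker smoothing at
  which the smallest-excursion items (the 12-14 degree scapular angles)
  still recover their commanded impairment to the advertised 2%
  tolerance — raw markerless jitter is considerably larger, which is a
  stated limitation for those items on real data.
* Force grids: five fingertip Gaussian blobs (thumb strongest at ~12 N,
  compact ~0.5-cell sigma) plus a broad low palm-contact area, ramping up
  over eight frames; the healthy (left-hand) print is column-mirrored.

The generator reproduces its own ground truth: a commanded `rom_scale`
of *s* is recovered by the measured ROM ratios within 0.02 on every angle
item, and profiles with scales 0 / 0.5 / 1 place every fuzzy input on the
core of the low / medium / high sets, so all 30 items score 0 / 1 / 2
exactly (verified over ten seeds in the test suite). What passing these
tests shows is that the *pipeline* is self-consistent end to end; it does
not validate the clinical mapping on real patients, where synergy
patterns, compensation strategies and tracker occlusions are far richer
than the minimum-jerk stand-ins used here.

## Numerical choices

* Defuzzification uses trapezoid quadrature over 2001 uniform points of
  `[0, 2]`; all membership breakpoints fall on grid points, so the
  centroid of piecewise-linear aggregates is exact to rounding. An
  all-zero aggregate (possible only with degenerate custom configs)
  returns the universe midpoint with a flag.
* Zero-phase filtering pads by odd reflection (3 x (order + 1) samples)
  to suppress edge transients; clips start and end near rest, so the
  reflection assumption is mild.
* Unequal-length traces are linearly resampled on a uniform `[0, 1]`
  parameterisation before the RMS deviation; the divisor is the common
  resample count.
* The weakest-link rule base makes the inference monotone at the rule
  level, but centroid defuzzification of clipped sets is only
  approximately monotone in the crisp value: as a clipped set grows, its
  centroid can shift slightly against the trend. The cumulative dip is
  bounded by about 0.056 on the `[0, 2]` scale for the default systems
  (measured over a dense sweep of all anchor combinations), and the
  discretised integer score is exactly monotone; the property tests
  assert both, with a 0.06 bound on the crisp value.
* Signed traces (axial rotation, pronation, wrist angle) are unwrapped
  before feature extraction; gimbal-adjacent samples inherit the
  deterministic assignment described above.
* The test-suite problem sizes — 5 s clips at 30 Hz, ten generator seeds,
  100 random inference systems for the engine oracle — were chosen to
  exercise every code path at interactive runtimes.

## Known limitations

* Bilateral referencing fails for bilateral impairment and inherits any
  deficit of the "healthy" limb.
* The severity cuts are defined for the 66-point scale; applying them to
  the 60-point automated total (the default) is conservative near the
  class boundaries.
* MV features at 30 Hz under a 12 Hz low-pass retain most tracker noise;
  real deployments with heavier jitter would need either a higher camera
  rate or stronger derivative smoothing than the published filter.
* The generator does not model pathological synergy coupling, occlusion
  dropouts, or soft-tissue artefacts; it is a measurement-chain test
  harness, not a patient simulator.
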