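# autofma

Automated scoring of upper-limb motor function on the Fugl-Meyer
Assessment (FMA-UE) scale, from markerless 3-D joint trajectories and
distributed pressure-grid grip recordings.

## Who this is for

Rehabilitation engineering and clinical movement-analysis groups that
record post-stroke patients with a depth-camera skeleton tracker
(Kinect-style body joints plus 21-point hand landmarks) and a 16x16
thin-film pressure grid, and want reproducible, rater-independent FMA-UE
item scores. The package scores the 30 automatable items (items 3-17 and
19-33; the two reflex items require a reflex hammer and are excluded),
producing per-item scores in {0, 1, 2}, a total in [0, 60], and a
hemiplegia severity class.

## The method in brief

Both limbs perform the same 21-motion protocol; the healthy limb is the
patient's own reference. For each angle-based item the pipeline extracts,
per sub-motion,

- ROM = max θ(t) − min θ(t) (range of motion, degrees),
- MV = mean |Δθ| · f_s (mean angular velocity, deg/s),
- δ = sqrt( Σᵢ Δdᵢ² / n ) — the RMS deviation between the resampled
  affected and healthy traces,

and forms the ratios AROM/HROM, AMV/HMV and δ/HROM. Reach items use
completion ratios (hand-to-hip, fingertip-to-nose); grasp items use the
thresholded sum of the per-cell maximum force grid, AFsum/HFsum;
coordination items use fingertip velocity/acceleration ratios. Joint
angles come from ISB-style joint coordinate systems (Y-X-Y shoulder Euler
decomposition), after zero-phase fourth-order Butterworth filtering at
12 Hz.

Each sub-motion's ratio vector is scored by a Mamdani fuzzy inference
system: three trapezoidal input sets (low/medium/high) per input, three
triangular output sets on [0, 2], min implication, max aggregation,
centroid defuzzification, and discretisation to {0, 1, 2}. Items with
several sub-motions combine the integer sub-scores with a weakest-link
rule:

    R = 0  if any sub-score is 0
    R = 2  if all sub-scores are 2
    R = 1  otherwise

Totals below 32 classify as severe, 32-57 as moderate, and 58-66 as mild
hemiplegia (clinical 66-point cuts; see the vignette for the 60-point
caveat).

Because no recordings are publicly deposited for this protocol, the
package includes a first-class synthetic generator of paired
healthy/affected sessions with controllable impairment (ROM/velocity/force
scaling, tremor, disabled fingers, tracker jitter), used throughout the
test suite.

## Worked example

```r
library(autofma)

# a moderately impaired synthetic patient: 55% range of motion, slowed
# movement, mild tremor, 45% grip force
prof <- impairment_profile(rom_scale = 0.55, velocity_scale = 0.7,
                           tremor_amplitude = 2, force_scale = 0.45,
                           seed = 42)
rec <- gen_recording(prof)
report <- assess(rec)
print(report)
#> <fma_report> subject synthetic (affected side: right)
#>   total 29/60 across 30 scored items -> severe hemiplegia
```

Every item carries its audit trail; for the cylinder-grasp item the
affected hand produced 43.7% of the healthy hand's effective grip force,
which the fuzzy system grades as partial performance:

```r
report$item_scores[["29"]]$features[[1]]$force_ratio
#> [1] 0.4367
report$item_scores[["29"]]$score
#> [1] 1
write_report(report, "report.json")
```

Recordings are plain JSON (schema in `inst/extdata/recording-schema.md`),
force frames JSON or CSV. Shell entry points live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --impairment 0.5 --seed 42 --out rec.json --forces forces.csv
Rscript inst/cli/assess.R --recording rec.json --out report.json
Rscript inst/cli/assess.R --registry-dump        # item/motion/feature table
```

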