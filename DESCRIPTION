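Package: autofma
Title: Automated Fugl-Meyer Assessment of Upper-Limb Motor Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the 30 automatable items of the upper-extremity
    Fugl-Meyer assessment (FMA-UE) from markerless 3-D body and hand
    joint trajectories and from 16x16 distributed pressure-grid grip
    recordings. Joint angles are reconstructed with ISB-style joint
    coordinate systems, conditioned with zero-phase Butterworth
    filtering, and summarised as range-of-motion, mean-velocity and
    side-to-side deviation features. Affected-to-healthy feature ratios
    feed per-item Mamdani fuzzy inference systems with centroid
    defuzzification; multi-sub-motion items are combined with a
    weakest-link rule, yielding per-item scores, a total score and a
    hemiplegia severity class. A synthetic paired recording generator
    with controllable impairment supports end-to-end validation without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
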