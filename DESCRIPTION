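Package: stsmap
Title: Sit-to-Stand Kinematics, EMG Envelopes, and 1D Permutation SPM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing sit-to-stand (STS) trials recorded with
    synchronized optical motion capture and bilateral surface EMG, aimed at
    side-to-side comparisons in hemiparetic populations. Provides kinematic
    event segmentation (Start, Lift-off, Stand, End), trunk and planar
    lower-limb joint angles, surface-EMG envelope extraction with spike
    clipping, time normalization of the movement cycle to 101 nodes,
    amplitude normalization per participant, exhaustive sign-flip permutation
    Statistical Parametric Mapping for paired designs with cluster-level
    inference, and Benjamini-Hochberg control of the false discovery rate
    across variables. A synthetic trial generator with known ground truth
    supports validation and power exploration without access to recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
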