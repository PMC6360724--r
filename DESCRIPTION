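Package: turnoutfoot
Title: Dance-Specific 3D Multi-Segment Foot Kinematics of Ballet Turnout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dance-specific three-dimensional
    multi-segment foot kinematics of ballet turnout: marker-trajectory IO and
    validation, zero-lag Butterworth filtering with Winter-style residual
    analysis, least-squares rigid pose estimation and CAST virtual-marker
    reconstruction, functional joint calibration (SCoRE centre, SARA axis),
    anatomical segment frames for tibia, hindfoot, midfoot, forefoot, first
    metatarsal, whole foot and pelvis, joint-coordinate-system Cardan angles
    including a first-MTPJ transverse-plane angle and navicular drop,
    demi-plie event extraction from saute trials, condition summaries and
    clinical classifications, repeated-measures ANOVA with Greenhouse-Geisser
    correction, stepwise regression and Pearson correlation, and a
    forward-kinematic synthetic marker generator with ground truth for
    end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
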