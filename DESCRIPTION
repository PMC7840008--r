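Package: evrlearn
Title: Full-Body Motor Learning Metrics for an Embodied-VR Billiards Task
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable analysis pipeline for short-term motor learning in a
    repeated billiards-shot task performed in embodied virtual reality.
    Provides a synthetic-cohort generator (shot outcomes, full-body joint
    kinematics, real/virtual validation pairs), a 2D shot-physics simulator
    with landmark-based coordinate-frame calibration, kinematic
    preprocessing (angular velocities, peak alignment, 1-s windows),
    task-space performance measures (directional error, success rate,
    robust t-distribution intertrial variability and its learning-corrected
    variant), body-space learning metrics (generalized variance, PCA
    dimensionality, manipulative complexity, velocity profile error), and
    exponential/double-exponential learning-curve fits, together with a
    small command-line interface tying the stages into end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
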