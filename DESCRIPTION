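Package: hindkin
Title: Multiplane Hind Limb Joint Kinematics for Quadruped Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for three-dimensional multiplane kinematic analysis of the
    quadruped (feline) hind limb from optical motion-capture marker
    trajectories. Builds anatomical segment coordinate systems for the pelvis,
    femur, tibia, and tarsus from skin-mounted markers, predicts a lateral
    stifle (knee) virtual marker from measured femur and fibula lengths using
    two projection techniques, decomposes hip, stifle, and tarsal joint
    rotations into flexion-extension, internal-external rotation, and
    abduction-adduction with joint coordinate systems, and compares the
    multiplane angles against a three-marker sagittal-plane model. Includes
    gait-cycle segmentation with stance/swing splitting and percent-cycle
    normalization, Woltring-style quintic spline gap filling, a minimal C3D
    and CSV trajectory reader/writer, a rotation-matrix alignment transform
    for validating skin-marker-derived angles against rigidly mounted marker
    triads, and a forward-kinematics generator of synthetic marker
    trajectories with prescribed joint-angle waveforms for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
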