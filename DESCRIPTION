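Package: gaitnorms
Title: Lower-Limb Sagittal Joint Angles from Norms of Foot Acceleration
    and Angular Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates hip, knee, and ankle sagittal joint angles over a
    gait cycle from only the per-sample norms of foot linear acceleration
    and angular velocity, the quantities a shoe-mounted inertial sensor can
    deliver independently of how the sensor is tilted. Provides the full
    pipeline: marker-based segment kinematics (foot local coordinate
    system, Cardan x-y-z joint angles, virtual foot marker, central
    difference acceleration, quaternion angular velocity), heel-contact
    detection from vertical ground-reaction force, gait-cycle extraction
    and 200-point time normalization, a standardize-then-PCA waveform
    codec with Kaiser component retention, a feedforward neural network
    regressor (Swish activation, dropout, Adam) with subject-level k-fold
    cross-validated hyperparameter tuning, waveform accuracy metrics, and
    a synthetic gait generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
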