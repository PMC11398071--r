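Package: vinewrist
Title: Wrist Posture Kinematics and Ergonomic Risk from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for quantifying wrist postures during
    viticultural pruning from three body-mounted inertial measurement units
    (hand, wrist joint, forearm). Parses and synchronizes 50 Hz
    accelerometer/gyroscope streams, estimates per-sensor orientation by
    complementary or Kalman fusion of gyro integration and accelerometer tilt,
    models the hand-wrist-forearm system with homogeneous transforms to extract
    wrist joint angles, detects cut events on acceleration traces, classifies
    postures into three ergonomic risk bands, and summarizes reference-angle
    validation trials. Includes a synthetic inertial-signal generator that
    emulates the laboratory reference-angle protocol and the simulated-vine
    pruning protocol so the whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
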