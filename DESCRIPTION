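Package: hemigait
Title: Predictive Simulation of Walking After Internal Hemipelvectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale neuromusculoskeletal modelling toolkit for predicting
    walking function after internal hemipelvectomy with custom prosthesis
    reconstruction. Provides reduced musculoskeletal walker models with
    surrogate muscle geometry and rigid-tendon Hill-type muscle mechanics,
    EMG processing and gait-cycle signal handling (OpenSim MOT/STO dialects),
    viscoelastic foot-ground contact with continuous stick-slip friction,
    recursive Newton-Euler inverse dynamics, muscle synergy extraction by
    non-negative matrix factorization with synergy extrapolation and
    contralateral mirroring, EMG-driven muscle-tendon calibration, direct
    collocation optimal control (Hermite-Simpson) for tracking and predictive
    gait problems, virtual muscle resection with a psoas-strength sweep, and
    clinical gait measures including the Bhargava muscle metabolic model and
    cost of transport. A seeded synthetic-gait generator supplies fully
    self-consistent fixture datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    signal,
    pracma,
    lhs,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
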