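Package: ofcbmi
Title: Two-Stage Neural Decoding of Reach Target and Trajectory with an
    Optimal Feedback Control Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a two-stage brain-machine
    interface (BMI) decoder for instructed-delay center-out reaching.
    Stage one predicts the intended target by maximum likelihood from
    delay-period spiking modeled as target-tuned homogeneous Poisson
    processes.  Stage two estimates the cursor trajectory with a
    feedback-controlled point process filter whose prior is a
    linear-quadratic-Gaussian (LQG) optimal feedback control model of the
    reach, run as a bank of parallel filters over candidate movement
    durations mixed by predictive likelihood.  Includes a random-walk
    point process filter ablation, a ridge-regression baseline on sliding
    window firing rates, a closed-loop task simulator with a ground-truth
    spiking population, and performance metrics (acquisition accuracy,
    RMS error, SNR, roughness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
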