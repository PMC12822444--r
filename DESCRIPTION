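Package: airtherm
Title: Airflow-Thermoelectric Response Modelling and Physiological Signal
    Recognition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward model of the voltage response of a wearable thermoelectric
    device to physiological airflow. Converts breathing, speech and cough
    airflow waveforms into upper-surface temperature and Seebeck voltage traces
    through a laminar flat-plate convective heat-transfer model with an exact
    piecewise-exponential integrator, and solves the coupled one-dimensional
    steady-state thermoelectric leg equations with a convective (Robin) upper
    boundary. Includes seeded generators of synthetic breathing, speech-airflow,
    cough-train and photoplethysmography-like heartbeat signals; short-time
    Fourier spectral features; a sliding-window severe-cough alarm rule; a
    fully-connected neural-network speech classifier; and a gradient-boosted
    multi-source (airflow plus heartbeat) fusion classifier for abnormal-state
    recognition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    nnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
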