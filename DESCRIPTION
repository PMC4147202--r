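Package: pcvsim
Title: Pressure-Controlled Ventilation Dynamics of a Single-Compartment
    Lung Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a pressure-controlled ventilation (PCV) circuit as a
    pure pneumatic system: an ideal ventilator pressure source driving a
    trapezoidal IPAP/EPAP waveform, a single equivalent orifice (throttle)
    carrying compressible subsonic flow, and an isothermal variable-volume
    container with constant compliance standing in for the lung. Provides
    the orifice mass/volume flow laws, a Reynolds-dependent Darcy friction
    model of respiratory resistance, fixed-step Runge-Kutta time integration
    of the coupled system, per-breath summaries, one-at-a-time parameter
    sweeps with peak-pressure threshold finders, compliance estimation from
    pressure/flow traces, seeded synthetic recordings, CSV/YAML input and
    output, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
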