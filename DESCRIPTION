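Package: circaphoto
Title: Circadian Clock Control of Photosynthesis Under Skeleton Photoperiods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forced transcription-translation feedback-loop model of the tea
    plant circadian clock and its photosynthetic outputs. Provides photoperiod
    schedules (including skeleton photoperiods), a nine-variable clock
    oscillator with Hill-function regulation and a Fourier-series LWD1 forcing
    term, six clock-controlled photosynthetic gene variables, an algebraic
    saturating map from clock state to photosynthetic parameters (net
    photosynthetic rate, stomatal conductance, intercellular CO2,
    transpiration), a classical fourth-order Runge-Kutta integrator with an
    entrain-then-switch protocol, peak-based rhythm statistics, cost-function
    parameter estimation, and generators for study-shaped synthetic
    RT-qPCR and stomatal-aperture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
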