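Package: nicodose
Title: Pharmacokinetic and Dopamine Kinetic Modelling for Nicotine
    Self-Administration Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing intravenous nicotine self-administration
    experiments in rats. Provides an infusion-event-driven two-compartment
    nicotine pharmacokinetic simulator with a closed-form biexponential
    disposition oracle and exposure metrics (peak, trough, AUC); parsing,
    schedule-semantics validation and rule-based acquisition classification
    of fixed-ratio operant session logs; Hill concentration-response fitting
    for activation and inhibition curves with bootstrap confidence
    intervals; Michaelis-Menten modelling of electrically evoked dopamine
    release and uptake measured by fast-scan cyclic voltammetry, including
    stimulation-intensity and frequency-response protocols and electrode
    calibration; synthetic-data generators that emulate the behavioural and
    electrochemical structure of such experiments; and an end-to-end
    pipeline chaining synthetic cohorts, classifiers and per-subject
    pharmacokinetic profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
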