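Package: swaepi
Title: Slow-Wave Activity and Epileptiform Event Analysis for Cortical Recordings
Version: 0.9.0
Authors@R:
    person("swaepi", "maintainers", email = "swaepi@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cortical excitability phenotypes in
    dual-hemisphere local field potential (LFP) recordings, chronic EEG/EMG
    and two-photon calcium imaging. Provides up/down-state segmentation of
    slow-wave activity, delta-band RMS and up-state transition slopes,
    beta-band burst and hypersynchronous (interictal-like) spike detection
    with phase locking to contralateral up states, multi-unit activity
    extraction, power-spectrum exponent estimation as an excitation:inhibition
    proxy, threshold-based Wake/NREM/REM sleep scoring, calcium-transient
    scoring with hyperactive-neuron statistics, and a seeded synthetic-data
    generator that produces ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
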