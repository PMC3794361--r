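Package: zfrig
Title: Virtual Rig for an Automated Zebrafish 5-Choice Serial Reaction Time Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A software re-creation of an automated operant-conditioning rig for
    testing impulse control in adult zebrafish with the 5-choice serial reaction
    time task (5-CSRTT). Provides camera-style fish presence detection by
    pixel-intensity variance inside regions of interest with Schmitt-trigger
    hysteresis, a synthetic-video fixture generator, the complete closed-loop
    training and trial state machine (habituation, magazine training, stimulus
    light training, 5-CSRTT at configurable pre-stimulus intervals), a stochastic
    fish-agent simulator with controllable impulsivity parameters and
    maximum-likelihood hazard recovery, and a behavioral-metrics analysis layer
    (accuracy, anticipatory and omission proportions, attrition screening,
    learning slopes, long-format exports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'zfrig-package.R'
    'utils.R'
    'AllClasses.R'
    'roi.R'
    'detect.R'
    'synthvideo.R'
    'schedule.R'
    'eventlog.R'
    'session.R'
    'agent.R'
    'metrics.R'
    'config.R'
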