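Package: oxyvib
Title: Accelerometer-Based Vibration Monitoring of ECMO Oxygenators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting incipient oxygenator thrombosis on venovenous
    extracorporeal membrane oxygenation (VV ECMO) from a triaxial accelerometer
    mounted on the oxygenator housing. Implements the vibration signal chain
    (omnidirectional norm of the three axes, frequency-domain brick-wall
    bandpass of 10-375 Hz, root-mean-square over non-overlapping 30-s windows),
    exact paired Wilcoxon signed-rank testing with median (min-max) cohort
    summaries, a synthetic cohort simulator emulating a two-phase porcine
    protocol (pump-speed sweep, then anticoagulation reversal with a lagged
    transmembrane-pressure response), and an end-to-end pipeline that produces
    tidy metric tables, cohort summary reports and vibration-versus-pressure
    detection lead times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
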