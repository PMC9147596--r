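Package: cardioephys
Title: Cardiac Cellular Electrophysiology Feature Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for murine cardiac electrophysiology:
    ECG interval metrics with two QT rate corrections, ventricular
    action-potential feature extraction including beat-to-beat variability
    of repolarization, fast sodium-current kinetics (Boltzmann activation
    and availability fits, inactivation time constants, window current,
    biexponential recovery from inactivation), late sodium-current
    quantification with drug percent-inhibition measures, and respiratory
    apnoea scoring from breath-event series. A synthetic-data generator
    provides ground-truth voltage-clamp sweep families, action-potential
    trains, ECG-like traces and breathing records for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
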