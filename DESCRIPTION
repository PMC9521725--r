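Package: deepmapr
Title: Automated Detection and Mapping of Decrement Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-processing workflow for ventricular tachycardia substrate
    mapping with decrement evoked potentials (DeEPs). Detects pacing trains
    and the premature extra-stimulus in multichannel intracardiac recordings,
    confirms myocardial capture from surface-ECG beat correlation, measures
    near-field evoked-potential latencies after the drive train (S1) and the
    extra-stimulus (S2), computes per-electrode decrement values, projects
    them as size-scaled spheres onto a 3D chamber voltage map, and scores
    algorithm output against expert annotations (sensitivity, specificity,
    Cohen's kappa, correction taxonomy). Includes a synthetic paced-recording
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
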