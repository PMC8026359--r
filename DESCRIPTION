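Package: knobmap
Title: Sulcus-Aligned TMS Mapping and Multimodal Analysis of the Precentral Hand Knob
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multimodal motor mapping of the precentral hand knob:
    construction of sulcus-aligned 5 x 7 transcranial magnetic stimulation
    (TMS) grids with locally perpendicular coil orientations, extraction of
    motor evoked potential (MEP) amplitudes and latencies from stimulus-locked
    electromyography, excitability maps and motor-hotspot localization,
    adaptive maximum-likelihood estimation of the resting motor threshold,
    a spatiotemporal hotspot rostrality index, movement-timing analysis of
    force traces from a paced visuomotor synchronization task, and the
    cohort-level correlation and group-contrast statistics that link cortical
    myelin content (quantitative MRI R1) to corticomotor representation and
    behavior. Includes a calibrated synthetic-cohort generator that emulates
    the statistical structure of such studies for validation and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
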