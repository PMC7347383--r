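Package: synpulse
Title: Expansion-Microscopy Synapse Quantification and LH Pulsatility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying synaptic appositions on GnRH neuron
    dendrites in expansion-microscopy volumes and for analysing pulsatile and
    surge modes of luteinizing hormone (LH) secretion from tail-tip bleed
    series. Includes a synthetic two-channel expanded-tissue image generator
    with ground-truth synapse placements, punctum detection and
    intensity-profile overlap classification with calibrated side-on/face-on
    thresholds, per-segment synaptic density reporting, an episodic LH
    secretion simulator, the nadir-to-peak >25% pulse-identification rule with
    summary statistics, a fold-rise surge classifier, and Mann-Whitney /
    Holm-Sidak group comparisons assembled into a combined report.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
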