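Package: gcannotate
Title: Five-Level Confidence Scoring for Non-Targeted GC-HRMS Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning and communicating confidence in compound
    annotations from non-targeted gas chromatography high-resolution mass
    spectrometry (GC-HRMS). Implements blank feature filtering, Kovats
    retention-index calculation and matching, forward and reverse dot-product
    spectral matching against MSP libraries, reverse high-resolution mass
    filtering (RHRMF) by subformula enumeration, molecular-ion and
    unequivocal-formula evidence, Kendrick mass-defect homologous-series
    detection, a five-level confidence schema (1, 2, 3, 4A/4B/4C, 5) with
    candidate ranking and multi-hit flagging, validation metrics against
    spiked-standard truth sheets, and a seeded synthetic-data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
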