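Package: fascreenkit
Title: Focal-Adhesion Screening and Image-Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("FA Screenkit", "Developers", email = "fascreenkit@example.org",
           role = c("aut", "cre"))
Description: Quantitative image analysis for focal-adhesion (FA) biology:
    segmentation and per-cell quantification of FAs from fluorescence
    microscopy fields, plate-level quality control and hit calling for
    high-content siRNA screens (Z'-factor, plate-wise Z-scores, secondary
    confirmation), cell-spreading and protrusive-area morphometry via
    marker-controlled watershed, and time-lapse FA dynamics (drift
    correction, overlap tracking, assembly/disassembly kinetics).  Ships a
    synthetic-microscopy generator that plants fields, plates and movies
    with exactly known ground truth so that every stage of the pipeline is
    testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
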