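Package: noxi
Title: Nocturnal Pulse-Oximetry Indices for Pediatric Sleep-Apnea Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing overnight pulse-oximetry (SpO2) recordings as a
    screening test for obstructive sleep apnea in children. Implements
    desaturation-event detection against a tracked baseline, the oxygen
    desaturation indices ODI3 and ODI4, desaturation clusters and the McGill
    oximetry score, together with two distribution- and regularity-based
    indices: the cumulative saturation area (CSA) and the SpO2 sample entropy
    (SSE). Includes paired pre/post statistical comparison, ROC analysis with
    Youden-optimal cutoffs, a synthetic overnight-recording simulator with
    ground-truth event annotations, and command-line entry points.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
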