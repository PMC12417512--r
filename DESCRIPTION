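Package: egflow
Title: Electrographic Flow Mapping of Atrial Fibrillation Sources from
    Basket Catheter Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs atrial activation wavefront propagation from
    60-second, 64-channel unipolar basket-catheter electrograms by optical
    flow (Horn-Schunck on an interpolated electrode grid), detects and tracks
    divergent (focal) and rotational flow singularities ("sources"),
    quantifies their prevalence and activity against clinical thresholds,
    analyses cycle-length entrainment by autocorrelation, and optimizes the
    clinically significant activity threshold against procedural outcomes via
    cross-validated Kaplan-Meier based statistics.  Includes a ground-truth
    simulator of basket recordings (focal/rotational sources with ON/OFF
    switching, planar background activation, far-field QRST, drift, noise,
    contact loss) and of outcome cohorts, so every pipeline stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    signal,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
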