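Package: sbrtaudit
Title: End-to-End Dosimetry Audit Analysis for Stereotactic Body Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for film-based end-to-end dosimetry audits of
    stereotactic body radiotherapy (SBRT) deliveries. Provides radiochromic
    film calibration with a time-dependent darkening correction and
    check-film linear-scaling quality control, medium-dependent (k_med) dose
    corrections tailored to dose-to-medium or dose-to-water reporting,
    landmark-based rigid registration of film to the planning grid with a
    dual-observer agreement check, global 2D gamma-index analysis with an
    exhaustive reference oracle, 1D distance-to-agreement at isodose lines,
    point- and region-dose difference metrics, conformity indices,
    multi-tier audit outcome scoring with failure-mode tagging, and cohort
    aggregation with pooled-variance significance testing. A synthetic-data
    module generates digital phantom planes, analytic planned doses for
    soft-tissue, spine and lung audit cases, simulated film scans through a
    forward film-response model, and perturbed deliveries with known
    injected error modes, so that every stage is testable without measured
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
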