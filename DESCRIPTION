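Package: dualmlc
Title: Dual-Layer Multi-Leaf Collimator Geometry Analysis and Dosimetric
    Leaf Gap Calibration for VMAT QA
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of volumetric
    modulated arc therapy (VMAT) delivered through a stacked-and-staggered
    dual-layer multi-leaf collimator (MLC).  Reads and writes DICOM RT Plan
    leaf sequences with two MLC layers, decomposes the staggered aperture
    into 5 mm strips to derive gap-width and leaf-trailing statistics,
    edits leaf sequences (single-layer conversion with tracking retraction,
    symmetric leaf opening, sweeping-gap test sequences), extracts the
    dosimetric leaf gap (DLG) from sweeping-gap readings by transmission
    correction and least-squares fitting, compares measured and calculated
    dose distributions by global dose difference and gamma index, and tunes
    the DLG empirically from the zero crossing of mean dose difference
    versus DLG.  A synthetic plan generator and a leaf-tip fluence engine
    with trailing-dependent tip transmission make the whole pipeline
    testable end to end without machine access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'rtplan.R'
    'dicom.R'
    'aperture.R'
    'editing.R'
    'dlgfit.R'
    'verification.R'
    'tuning.R'
    'synthetic.R'
    'study.R'
    'RcppExports.R'
    'dualmlc-package.R'
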