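Package: rtcompare
Title: Multi-Observer Radiotherapy Structure Comparison and Dosimetric
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing radiotherapy target-volume delineations
    from multiple observers and evaluating the dosimetric consequences of
    delineation differences. Implements voxel-grid structure masks with
    NIfTI input/output and polygon rasterization, consensus ("mean
    structure") generation by per-voxel vote with a 0.5 threshold,
    surface dice similarity coefficients at a distance tolerance,
    CTV-to-PTV margin expansion by exact Euclidean distance, a
    dose-volume-histogram engine (Dmean, VxGy, D98%, ICRU-50 treated and
    irradiated volumes, dose outside the PTV), and guideline coverage
    verdicts. A synthetic-data module generates an anthropomorphic
    thorax phantom, multi-observer contour perturbations, and simplified
    tangential and AP-PA dose distributions so the full pipeline can be
    exercised end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
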