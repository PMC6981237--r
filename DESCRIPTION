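Package: ratiomics
Title: Ion-Intensity-Ratio Fingerprinting of Mass Spectra with
    Genetic-Algorithm Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for discriminating sample classes from shotgun
    (non-chromatographically resolved) mass-spectrometry fingerprints.
    Raw multi-scan spectra are summed over a scan window, baseline-corrected
    by local regression, and reduced to validated peak tables; peaks are
    aligned across samples by complete-linkage hierarchical clustering on
    m/z; consensus features are annotated against an exact-mass compound
    database with signed ppm errors. Class discrimination uses ordered
    ion-intensity ratios, which are invariant to per-injection global
    intensity drift; a genetic algorithm selects minimal ratio subsets by
    cross-validated linear discriminant accuracy, with multi-stage ranking
    on independent validation data and a random-forest benchmark. Includes
    a synthetic spectrum and cohort generator with planted discriminant
    ratios for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mzR,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
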