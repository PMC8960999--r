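Package: cdvim
Title: Connectivity-Defined Localisation of the Ventral Intermediate Thalamic Nucleus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic streamline tractography of the dentato-thalamo-cortical
    pathway on synthetic fibre phantoms, adaptive thresholding of the
    tract-thalamus intersection to localise the ventral intermediate nucleus
    (Vim), stereotactic atlas-coordinate targeting from AC-PC landmarks, and a
    statistics suite for cohort centroid variability: displacement and
    dispersion metrics, paired hemispheric position and Pitman-Morgan variance
    tests, confound regression screens, principal directions of variance,
    Jacobian-based regional volumetrics, and test-retest comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
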