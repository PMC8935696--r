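Package: psdflow
Title: Parasagittal Dural Space Volumetry and Aqueductal CSF Flow Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the parasagittal dural (PSD) space and
    cerebrospinal-fluid (CSF) dynamics across the adult lifespan from
    multi-modal head MRI. Implements ECG-gated phase-contrast flow
    quantification through the cerebral aqueduct with velocity-encoding
    (venc) aliasing correction; semi-supervised PSD segmentation combining
    a compact patch-based 3D U-Net with Gaussian-mixture maximum a
    posteriori voxel labeling of the T2-weighted signal; intracranial and
    CSF/gray/white tissue volumetry by expectation-maximization intensity
    classification; and the cohort statistics used in lifespan studies
    (multivariate linear models with Wald intervals, Spearman rank
    correlation, Kruskal-Wallis age-group tests, Benjamini-Hochberg FDR).
    A seeded synthetic-data module generates head phantoms, gated
    phase-contrast series and Gaussian-copula cohorts with ground truth
    for every stage, so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
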