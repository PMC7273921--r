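Package: siscom
Title: Ictal-Interictal SPECT Subtraction Analysis for Epileptogenic Zone Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Subtraction ictal-interictal SPECT analysis (SISCOM) for localizing
    the epileptogenic zone in focal epilepsy. Provides NIfTI volume handling and
    brain masking, rigid registration of the interictal to the ictal volume by
    mutual-information maximization, whole-brain intensity normalization,
    voxel-wise subtraction and z-score standardization, cluster extraction above
    a z threshold with epileptogenic-zone calling, a SPECT-like brain-perfusion
    phantom simulator with known ground truth for validation, and the agreement
    statistics (Cohen's kappa, McNemar, Mann-Whitney) used to compare imaging
    localizations against a clinical reference standard.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
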