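Package: rsfnc
Title: Group ICA, Dual Regression and Functional Network Connectivity for
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for resting-state fMRI network analysis:
    group spatial independent component analysis (two-stage PCA reduction,
    minimum description length order selection, infomax), dual-regression
    back-reconstruction of subject maps and time courses, spectral-power
    component selection, voxelwise one- and two-sample t statistics with
    Benjamini-Hochberg false discovery rate control, and functional network
    connectivity via constrained maximal time-lagged correlation with
    subsystem reorganization. Ships a synthetic multi-subject BOLD
    generator with known spatial networks, lagged couplings and group
    effects for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
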