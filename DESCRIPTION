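Package: mousebold
Title: Atlas-Based Activation Mapping for Awake-Mouse BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise BOLD activation analysis for awake-mouse block-design
    fMRI. Implements percent-signal-change contrasts between control and
    stimulation windows with Welch t-tests and Benjamini-Hochberg false
    discovery rate control, 6-DOF rigid-body motion estimation, 9-parameter
    affine subject-to-atlas registration with stored inverses, atlas-based
    region-of-interest volumetry and normalized volume of activation,
    nonparametric genotype group comparisons (Kruskal-Wallis, Mann-Whitney U),
    Fisher's protected LSD volume contrasts, ROI time-course analysis with
    mixed repeated-measures ANOVA, and a synthetic phantom generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
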