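Package: vbmli
Title: Voxel-Based Morphometry Correlates of Autobiographical Memory with
    Lateralization-Index Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A mass-univariate pipeline relating gray-matter volume to
    autobiographical-memory performance. Provides a synthetic cohort
    simulator producing aligned modulated gray-matter-like volumes with
    planted score-volume couplings, a behavioral module for cue-word
    autobiographical memory scores (ANCOVA with an age covariate,
    repeated-measures group-by-period interaction, Fisher's LSD post-hoc
    tests), a voxelwise general linear model with Gaussian smoothing,
    t-contrasts and uncorrected/FDR/Bonferroni thresholding, cluster
    extraction with extent filtering and Talairach reporting, and
    lateralization-index curves over a threshold ladder for left-right and
    anterior-posterior hippocampal comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
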