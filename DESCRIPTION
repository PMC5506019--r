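Package: brainheart
Title: Brain-Heart Coupling and Functional Connectivity Analysis for
    Simultaneous fMRI and Pulse Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how brief affective interventions modulate
    brain functional connectivity and heart rate when functional MRI and
    fingertip photoplethysmography (PPG) are recorded simultaneously.
    Implements PPG beat detection and instantaneous heart-rate extraction,
    temporal preprocessing of 4D BOLD images (volume trimming, Gaussian
    smoothing, nuisance regression, band-pass filtering), seed-based
    connectivity with Fisher r-to-z maps, temporal-concatenation group
    independent component analysis with dual regression and template
    matching, sliding-window dynamic connectivity, a windowed brain-heart
    synchronization statistic, and a group-level battery (paired and
    one-sample t maps, repeated-measures ANOVA with Bonferroni post-hocs,
    covariate regression, permutation max-cluster-size family-wise error
    control, and Benjamini-Hochberg false discovery rate on network edges).
    A synthetic cohort generator with injectable ground-truth effects makes
    every stage testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
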