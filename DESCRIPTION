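Package: twdfc
Title: Track-Weighted Dynamic Functional Connectivity Parcellation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements track-weighted dynamic functional connectivity
    (tw-dFC): sliding-window BOLD correlations sampled at streamline
    endpoints are propagated onto the white-matter voxels the streamlines
    traverse, yielding a hybrid structural-functional 4D signal. On top of
    this signal the package provides connectivity-based parcellation of a
    seed region (subject-level k-means with consensus clustering across
    subjects), cluster-number validity metrics (silhouette, normalized
    variation of information over split-half resamples, Dice reproducibility),
    anatomical and functional characterization (atlas overlap, maximum
    probability maps, preferential connectivity with permutation-based
    family-wise error inference, lateralization indices), and
    meta-analytic-style decoding by track-weighting scalar term maps.
    A synthetic-scene generator produces multi-subject datasets with planted
    cluster structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
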