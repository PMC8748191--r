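Package: gutbraincov
Title: Gut Microbial Balance Signatures and Seed-Based Structural Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links compositional gut-microbiome signatures to grey-matter
    structural covariance networks. Implements log-contrast balance statistics
    for relative-abundance data, forward (selbal-style) balance selection with
    cross-validated signature-size choice and robustness summaries, median-split
    dysbiosis stratification with group comparisons of cognitive and mood
    scores, seed-based voxel-wise structural covariance general linear models
    with sequential Gram-Schmidt covariate orthogonalization, threshold-free
    cluster enhancement (TFCE), and max-statistic permutation family-wise error
    inference including small-volume correction. Ships synthetic cohort
    generators (phylum abundance tables with a planted BMI-associated balance,
    and modulated grey-matter volume stacks with planted seed-covariance
    networks) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
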