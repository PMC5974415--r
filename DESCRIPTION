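Package: skelex
Title: Skeleton-Based White-Matter Statistics and Atlas Gene Expression Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imaging-transcriptomics pipeline for small-animal diffusion MRI.
    Implements tract-based spatial statistics on fractional-anisotropy maps
    (mean-FA skeletonization, skeleton projection, permutation-based group
    tests with threshold-free cluster enhancement), a staged 12-parameter
    affine alignment of in situ hybridization expression volumes into a
    common template space, and a cluster-versus-skeleton rank-sum test that
    identifies genes overexpressed where white matter differs between groups.
    Ships a synthetic phantom generator emulating a sex-by-genotype mouse
    cohort and atlas-style expression energy volumes so the full pipeline is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
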