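Package: prefmorph
Title: Economic Preference Estimation and Surface-Based Morphometry Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of risk tolerance (power utility)
    and delay discount rates (hyperbolic discounting) from binary choice
    data with a softmax choice rule; subject exclusion rules and model-free
    choice measures; triangulated-mesh utilities (icosphere construction,
    geodesic discs, FWHM-calibrated smoothing, spherical ROI masks, GIFTI
    and plain-array surface I/O); mass-univariate vertex-wise regression
    with threshold-free cluster enhancement (TFCE), Freedman-Lane
    permutation inference and FDR correction; directional conjunction
    analysis, cluster reporting and peak-area regression; plus synthetic
    cohort generators (choices, covariates, vertex metric maps with planted
    effects) so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
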