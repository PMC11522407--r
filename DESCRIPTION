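Package: spotclone
Title: Deconvolution of Cancer Clone Proportions in Spatial Transcriptomics Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian deconvolution of the clonal composition of spatial
    transcriptomics (ST) spots from somatic point-mutation read counts.
    Given clone genotypes and prevalences reconstructed from bulk DNA-seq,
    alternated/total read counts at variant sites in ST spots, and per-spot
    cell-count priors from histology images, a Metropolis-Hastings-within-
    Gibbs sampler over a Beta-Bernoulli feature-allocation model infers the
    fraction of each spot occupied by each clone, refined cell counts, and
    per-variant per-cell expected coverage. Includes a calibrated simulator
    with known ground truth, moment-based hyperparameter estimators,
    evaluation statistics (mean average error, major-clone accuracy,
    adjacent/distant spot-pair correlation), and a non-negative regression
    stage that recovers clone-specific gene-expression profiles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
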