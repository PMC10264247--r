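Package: chromunmix
Title: Deconvolution of Multiplexed Single-Cell Histone Modification Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probabilistic deconvolution of single-cell chromatin count
    profiles obtained by incubating cells with two histone-modification
    antibodies simultaneously. Cluster-specific multinomial profiles are
    learned from single-incubated training cells with a collapsed-Gibbs
    latent Dirichlet allocation on genomic bins; each double-incubated
    cell is then assigned to its most likely cluster pair, its mixing
    weight estimated by maximum likelihood, and every cut fragment
    attributed to one of the two marks. Includes a Poisson count
    simulator with controlled genome-wide overlap between marks, a
    continuous-pseudotime variant of the mixture likelihood with
    standard errors from the observed information, first-order chromatin
    velocity kinetics, and evaluation metrics (pair-assignment confusion
    and locus-level calibration of assignment probabilities).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
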