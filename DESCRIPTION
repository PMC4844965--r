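Package: facepatches
Title: Hierarchical Face-Processing Model with View- and Identity-Selective Layers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: Implements a hierarchical computational model of primate face
    processing. An HMAX-style front end (Gabor simple cells, local and global
    max pooling, prototype-tuned radial-basis units) feeds a view-selective
    layer (VSL) of Gaussian units grown under an adaptive-resonance vigilance
    rule and an identity-selective layer (ISL) wired by a temporal trace rule.
    The package bundles a parametric multi-view synthetic face generator,
    the sequential training protocol with evaluation-gated unit growth,
    representational-similarity statistics (view and identity selectivity
    indices, degree of invariance, discriminability scores, composite-face
    hit rates, cross-view identification), and runners for the standard
    face-perception experiments: representational geometry, canonical views,
    inversion, in-plane rotation, composite faces, and the other-race effect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    e1071,
    withr,
    tibble,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
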