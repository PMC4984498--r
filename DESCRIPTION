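Package: sdmdiv
Title: Sex-Determining Mechanisms, Transition Rates, and Diversification on
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Macro-evolutionary analysis of a binary sex-determining mechanism
    (genotypic versus temperature-dependent sex determination) on dated
    phylogenies. Implements the two-state Markov (Mk2) likelihood with
    maximum-likelihood fitting, likelihood-ratio tests, slice-sampling MCMC and
    marginal ancestral-state reconstruction; the binary-state speciation and
    extinction (BiSSE) likelihood with skeletal-tree sampling fractions,
    constrained transition-rate and diversification tests; species-richness
    independent contrasts (MacroCAIC) with minimal-clade-size filtering; a
    generic parametric-bootstrap harness for null distributions of
    diversification statistics; and single- and two-regime Brownian-motion and
    Ornstein-Uhlenbeck models of continuous trait (lifespan) evolution over a
    regime-painted tree. Includes birth-death tree, binary-character and
    regime-trait simulators that generate turtle-like and lizard-like synthetic
    data sets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phytools,
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
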