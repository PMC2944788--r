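Package: traitarch
Title: Complex-Trait Architecture and Genomic Prediction in Half-Sib Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetic architecture of quantitative traits
    in livestock-style half-sib populations and its consequences for genomic
    prediction. Includes a forward-in-time Wright-Fisher simulator of dense SNP
    panels with realistic linkage disequilibrium, genotype quality control,
    genomic relationship matrices, REML variance-component estimation, GBLUP
    and BayesA (Gibbs sampling with a scaled inverse-chi-square prior on
    SNP-specific variances) genomic prediction, single-SNP association scans
    with a random sire effect, estimation of the distribution of variance
    explained by 50-SNP chromosome segments via permutation-calibrated EM
    deconvolution, and deterministic predictions of genomic breeding-value
    accuracy under normal and leptokurtotic effect distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
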