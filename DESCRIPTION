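Package: nemadapt
Title: Quantifying Excess Adaptive Evolution in Nematocyst Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how much more adaptive evolution nematocyst proteins
    (NEMs) experience than matched non-nematocyst proteins across cnidarians.
    Implements gene-wide selection-evidence thresholding (BUSTED p-values),
    per-gene adaptation as the mean proportion of positively selected codons
    over branches (aBSREL rate-class weights), a dN-matched permutation
    sampler for building covariate-matched non-NEM reference sets, the
    excess-of-adaptation statistic with permutation p-values and confidence
    intervals, alpha/X calibration of the matching scheme against dN/dS
    moments, GO-stratified excess, Fisher's exact enrichment of positive
    selection, ortholog core-set and exclusive-intersection arithmetic, and
    macroevolutionary lag between paired chronograms. A seeded synthetic-data
    generator emulates gene-level selection statistics with known ground
    truth so the whole pipeline is testable without external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
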