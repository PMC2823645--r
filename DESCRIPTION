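Package: rcpcr
Title: Quantification and Inference for Real-Competitive PCR Gene
    Expression Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative gene expression by real-competitive
    PCR (rcPCR/QGE): titration-curve fitting on logit-transformed peak-area
    frequencies, interpolation of the equivalence (EC50) concentration,
    housekeeping-normalized fold changes between treatment groups with
    bootstrap bias, standard error, confidence intervals and p-values,
    allele-specific expression ratios from two-allele assays, and
    candidate-gene association of a log-normal phenotype with genotype
    least-squares means, overall F-tests and Hardy-Weinberg checks. A
    synthetic competitive-PCR data generator emulates competitor dilution
    ladders, genotypes under Hardy-Weinberg equilibrium and log-normal
    phenotypes so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    emmeans,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
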