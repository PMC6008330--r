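Package: methmediate
Title: Methylation-Mediated Genetic Risk: DMR Discovery, Causal Inference
    Testing and Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of whether DNA methylation mediates genetic
    risk for a binary disease phenotype. Implements bump-hunting detection of
    differentially methylated regions with permutation family-wise error
    control, methylation and expression quantitative trait locus scans,
    case-control association with maxT permutation adjustment, a logistic
    Causal Inference Test that classifies genotype-methylation-phenotype
    triplets as mediated, consequential or independent, two-sample MR-Egger
    regression with correlated instruments, Steiger directionality with a
    measurement-error reliability ratio, conditional association, genomic
    control and fixed/random-effects meta-analysis. A synthetic-cohort
    generator with known causal structure (block-LD genotypes, cell-mixture
    confounded methylation, mediation / reverse-causation / pleiotropy
    phenotypes) supports power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
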