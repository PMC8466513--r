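Package: pigeonrace
Title: Forced PCR-RFLP Genotyping and Genotype-Performance Association in
    Racing Pigeons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for candidate-gene association studies of
    homing-pigeon racing performance. Provides in-silico forced PCR-RFLP
    (dCAPS) assay design and genotype calling from restriction fragment
    patterns, genotype and allele frequencies with a Hardy-Weinberg
    equilibrium chi-square test, rank-based ace-points scoring of race
    records, the additive relationship matrix from a multi-generation
    pedigree by the tabular method, and a restricted maximum likelihood
    animal model with a permanent-environment effect for repeated race
    records, genotype least-squares means and pairwise contrasts. A
    simulation module generates pedigrees, Mendelian genotypes and race
    outcomes with known effect sizes and variance components so every stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
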