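Package: hwuni
Title: Genetic Evaluation of Harvest-Weight Mean and Uniformity with Indirect Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sire-dam double hierarchical generalized linear models (DHGLM) for
    the joint genetic evaluation of harvest weight and its uniformity (the
    genetic variance in residual variance) in group-reared aquaculture
    populations such as Pacific white shrimp. Fits the coupled mean and
    residual-variance models by iteratively reweighted average-information REML
    over pedigree (A) or single-step genomic (H) relationship matrices, with
    optional indirect (social) genetic effects for cage-mates. Includes
    construction and validation of three-families-per-cage (3FAM) test designs,
    gene-drop simulation of pedigrees, genotypes and phenotypes with stored
    truth, SNP quality control, VanRaden genomic relationship matrices,
    derived genetic parameters (total breeding value variance, uniformity
    heritability, genetic coefficient of variation), and k-fold cross-validated
    prediction accuracy comparing pedigree and single-step genomic BLUP.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
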