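Package: hornpred
Title: Genomic Prediction of Polled and Horned Phenotypes in Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and genomic prediction of categorical horn phenotypes
    (polled, knobs, scurs, horned) in half-sib sheep populations segregating a
    causal insertion locus with sex-dependent penetrance. Provides gene-dropping
    simulation of phased genotypes with tunable linkage disequilibrium around
    the causal locus, pedigree (A), genomic additive (G) and dominance (D)
    relationship matrices, a linear mixed-model engine with ML/REML variance
    components, five sex-by-gene mode-of-inheritance models compared by AIC,
    single-SNP and multi-SNP haplotype predictors, GBLUP with back-solved
    marker effects, and cross-validation, within-family and across-family
    validation designs with per-sex Pearson accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
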