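Package: facesym
Title: Facial Asymmetry, Heterozygosity and Genotype Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying developmental imprecision from 3D facial
    landmarks and SNP genotypes. Decomposes landmark asymmetry into
    directional and fluctuating components via reflection-relabeling and
    generalized Procrustes analysis (object symmetry), computes the
    homozygosity-by-loci (HL) index from biallelic genotype panels, and fits
    association models linking asymmetry to demographics, HL and
    reference-coded genotypes: ordinary least-squares models with stepwise
    interaction pruning and an ANOVA-style regression tree over many SNPs.
    Includes a synthetic cohort generator with plantable directional
    asymmetry, fluctuating-asymmetry variance and heterozygosity effects, so
    every stage of the pipeline can be validated against a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    optparse,
    withr
Config/testthat/edition: 3
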