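Package: augwas
Title: Genetic Architecture Dissection for Complex Traits in Augmented Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end association-analysis toolkit for quantitative traits
    measured in unreplicated augmented field trials, as used in plant breeding
    programs. Provides adjusted means for augmented complete block designs,
    average-information REML variance components with Cullis heritability,
    genomic relationship matrices and bivariate genetic correlations,
    single-trait genome-wide association scans (single-locus mixed model plus
    FarmCPU-style and BLINK-style multi-locus engines) with principal-component
    and trait covariates, multi-trait joint F-tests for pleiotropy, and
    downstream marker consistency, linkage-disequilibrium binning and
    favorable-allele pyramiding summaries. Includes a genotype and trial
    simulator with population structure, LD blocks and genotype-by-environment
    interaction so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
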