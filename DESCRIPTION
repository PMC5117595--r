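Package: pedvc
Title: Pedigree-Based Variance Components and Measured-Genotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based quantitative genetics for field studies: reads and
    validates LINKAGE/PED pedigrees with phenotype and genotype tables,
    computes additive genetic relationship matrices by the tabular method,
    fits univariate and multivariate additive-genetic plus residual
    variance-components mixed models by REML or ML (heritabilities, genetic
    and environmental correlations, fixed covariate and measured-genotype
    effects with Wald tests), partitions genetic variance attributable to
    individual loci, and provides supporting epidemiological statistics
    (albuminuria classification, MDRD eGFR, relative risks, pairwise
    correlation matrices, Hardy-Weinberg and transmission-disequilibrium
    tests). Includes a gene-dropping simulator that generates community-style
    pedigree studies with configurable heritabilities, trait correlations,
    allele frequencies and genotype effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
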