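Package: rvkt
Title: Rare Variant Kinship Test for Family-Based Quantitative Trait Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens quantitative traits measured in family-based studies for
    the signature of a rare, modest-to-large-effect variant: excess relatedness
    (elevated mean pairwise kinship) among individuals in a tail of the trait
    distribution. Pedigrees are parsed from PLINK-style PED/FAM files, exact
    kinship coefficients are computed by the standard recursive tabular method,
    and the null distribution of the tail-kinship statistic is generated by
    simulating purely polygenic traits conditional on the observed pedigrees.
    Includes gene-dropping simulation of a biallelic rare variant for power
    evaluation, rank-based inverse normal transformation and covariate
    adjustment of phenotypes, narrow-sense heritability estimation, and an
    effective-number-of-tests multiple-testing correction for screens of many
    correlated traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
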