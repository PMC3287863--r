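Package: popfam
Title: Combining Population- and Family-Based Genetic Association Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements three statistics for jointly analysing unrelated
    case-control subjects and case/control-parent trios at single SNPs under
    an additive genetic model: a weighted least-squares combination of the
    conditional-on-parental-genotypes (CPG) relative-risk estimate with the
    case-control logistic log odds ratio, guarded by a Wald homogeneity
    pre-test; a principal-components residual covariance test with a
    family-robust variance; and a score test that sums an adjusted
    population-based component over unrelated subjects with a Mendelian
    within-family component over trio offspring.  A synthetic mini-exome
    generator (rare-skewed allele frequency spectrum, liability-threshold
    phenotypes, Hardy-Weinberg founders, Mendelian trio transmission) and a
    replicate-based simulation harness reproduce the type-I error and power
    evaluation design for mixed family/population samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
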