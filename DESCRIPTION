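Package: permforge
Title: Permutation Testing for Quantitative-Trait Genome-Wide Association
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: maxT and adaptive permutation testing for continuous phenotypes
    over PLINK binary genotype data (.bed/.bim/.fam). Per-variant association
    is scored with the simple-regression F statistic; family-wise error is
    controlled either by the maxT procedure (null distribution of
    per-permutation maximum statistics) or by adaptive early stopping of
    uninteresting variants on a growing checkpoint schedule. The permutation
    kernel is a blocked genotype-matrix by phenotype-vector product with
    one-time covariate residualization, mean imputation of missing
    genotypes, and an optional emulated fixed-point arithmetic mode; result
    objects carry tidy(), glance() and autoplot() methods. A synthetic-data
    generator produces PLINK-format fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
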