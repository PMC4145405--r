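Package: hcscan
Title: Higher Criticism Scans for Group-Based Rare-Variant Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Group-based association testing of sequencing dosage data
    against a quantitative trait. Variants are grouped into fixed genome
    windows or user-supplied gene intervals; rare variants are collapsed
    into pseudo-variants by equal-weight or Madsen-Browning weighted sums;
    group significance is measured by the Higher Criticism statistic over
    ordered per-variant p-values, the minimum p-value (minP) statistic, or
    a flat-weight sequence kernel association test (SKAT), each calibrated
    by per-window permutation. Includes a synthetic genotype/phenotype
    simulator with a rare-skewed allele frequency spectrum and block LD,
    and evaluation utilities (genomic inflation factor, QQ tables, power
    curves, AUC, per-window power).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
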