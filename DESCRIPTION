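Package: methcna
Title: Integrative Analysis of DNA Methylation and Copy-Number Alteration in Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative statistical analysis of tumor DNA-methylation profiles
    and SNP-array copy-number data: recursively partitioned beta-mixture (RPMM)
    clustering of methylation beta values, hidden-Markov-model copy-number-state
    calling from log2 ratios, a per-tumor copy-number burden statistic with a
    permutation Kruskal-Wallis test of association with methylation class, a
    locus- and gene-level methylation/copy-number Pearson correlation screen
    with permutation p-values and Storey q-values, tumor-versus-normal
    alteration tests, Ward/Hamming clustering with high/low CNA dichotomization,
    and LINE-1 global-methylation group comparison. Includes a synthetic-cohort
    generator with ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
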