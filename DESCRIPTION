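Package: extremevar
Title: Extreme-Phenotype Sequencing Association Analysis with
    Rare-Variant Burden Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case/control association analysis for targeted resequencing
    studies that sample the extremes of a quantitative trait. Provides
    covariate adjustment and quartile-based selection of hyper- and
    hypo-phenotype subjects within ancestry strata, minor-allele-frequency
    stratified single-variant tests (two-sided Fisher exact for rare
    variants, additive logistic regression for common variants),
    rare-variant burden tests (carrier collapsing with a 1-df chi-square,
    the Madsen-Browning weighted-sum rank test with a permutation null,
    and the C-alpha dispersion test), EM-based pairwise linkage
    disequilibrium estimation from unphased genotypes with greedy tag-SNP
    selection, and a synthetic genotype/phenotype cohort generator so the
    full pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
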