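Package: epidiv
Title: Epiallele Diversity Analysis for Targeted Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-molecule ("epiallele") DNA methylation analysis of targeted
    deep bisulfite amplicon sequencing. Takes merged amplicon reads to filtered
    per-molecule methylation profiles (0/1/2 calls per CpG), builds rarefiable
    sample-by-epiallele count tables, and computes epiallele class distributions,
    per-site and regional methylation averages, spike-in-calibrated non-CpG (CpH)
    methylation, alpha and beta diversity (observed epialleles, Shannon index,
    Bray-Curtis, PCoA) and group inference (ANOSIM, Cramer two-sample test,
    per-site t tests with Bonferroni correction, ANOVA with Tukey post-hoc).
    Includes a fully seeded synthetic-data generator emulating a multi-region
    brain cohort design, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    tools,
    vegan,
    biomformat,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
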