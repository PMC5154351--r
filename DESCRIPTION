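Package: reodiff
Title: Individual-Level Differential Expression of miRNAs from Rank Reversals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls differential expression of miRNAs in individual tumor
    samples from within-sample relative expression orderings (REO). Pairs of
    miRNAs whose ordering is stable across normal samples but significantly
    reversed across tumors (Fisher's exact test, Benjamini-Hochberg FDR) are
    mined into small per-miRNA reference panels of low-variability partners;
    a majority vote over a panel yields an up/down/none call per patient
    without any between-sample normalization. Includes the evaluation
    protocols (paired-sample precision, spike-in simulation with per-miRNA
    sensitivity/specificity/F-score), downstream analyses (subtype
    enrichment, mutually exclusive miRNA-target screening against copy-number
    alterations, survival grouping), synthetic cohort generators, and readers
    and writers for the tabular formats involved (expression TSV, GMT gene
    sets, interaction tables, copy-number ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
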