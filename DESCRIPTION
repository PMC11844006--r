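Package: gxmscan
Title: Genome-Wide SNP-by-Methylation Interaction Scans on Transcript Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to detect interactions between promoter SNPs and DNA
    methylation (G x M) in the regulation of transcript-level expression.
    Builds strand-aware promoter windows from transcript annotation,
    enumerates (transcript, SNP, CpG probe) triplets, fits nested linear
    models with a likelihood-ratio test for the interaction term,
    controls the false discovery rate genome-wide, reduces correlated
    signals by greedy LD clumping, and characterises hits through
    regulatory-peak enrichment, methylation-stratified genotype effects,
    and case-control or quartile differential expression. Includes a
    seeded synthetic multi-omics cohort generator (genotypes in
    Hardy-Weinberg proportions with tunable LD, beta-distributed
    methylation, log-linear expression with planted interaction effects)
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
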