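# prep + scan a simulated cohort with the pipeline's standard stages
scan_cohort <- function(coh, ...) {
  tri <- suppressMessages(apply_qc(
    enumerate_triplets(promoter_windows(coh$annotation), coh$genotypes,
                       coh$methylation),
    coh$genotypes, coh$expression))
  suppressMessages(run_scan(tri, coh$genotypes, coh$methylation,
                            coh$expression, coh$phenotypes, ...))
}
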