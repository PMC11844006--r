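#' Configuration for the full analysis pipeline
#'
#' Collects every threshold and path the pipeline uses; the validated
#' config is serialised verbatim into the output manifest.
#'
#' @param vcf,gtf,meth,expr,probes,pheno optional input file paths (VCF,
#'   GTF, methylation TSV, expression TSV, probe-annotation TSV, phenotype
#'   TSV). Omit them when passing an in-memory cohort to
#'   [run_full_analysis()].
#' @param out_dir optional output directory; when set, stage tables and a
#'   `manifest.json` are written there.
#' @param upstream,downstream promoter window extent in bp.
#' @param maf_min,tpm_median_min QC thresholds (strict).
#' @param fdr_primary,fdr_replication significance thresholds.
#' @param r2_threshold,clump_group LD clumping parameters.
#' @param covariates covariate column names for the scan.
#' @param transform expression transform.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `gxm_pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, gtf = NULL, meth = NULL, expr = NULL,
                            probes = NULL, pheno = NULL, out_dir = NULL,
                            upstream = 2000, downstream = 200,
                            maf_min = 0.05, tpm_median_min = 0.1,
                            fdr_primary = 0.05, fdr_replication = 0.1,
                            r2_threshold = 0.8,
                            clump_group = "transcript-probe",
                            covariates = c("sex", "age"),
                            transform = "log2p1", seed = 1) {
  if (upstream < 0 || downstream < 0) stop("window extents must be >= 0")
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)")
  if (tpm_median_min < 0) stop("tpm_median_min must be >= 0")
  for (f in c(fdr_primary, fdr_replication))
    if (f <= 0 || f >= 1) stop("FDR thresholds must be in (0, 1)")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]")
  structure(list(vcf = vcf, gtf = gtf, meth = meth, expr = expr,
                 probes = probes, pheno = pheno, out_dir = out_dir,
                 upstream = upstream, downstream = downstream,
                 maf_min = maf_min, tpm_median_min = tpm_median_min,
                 fdr_primary = fdr_primary,
                 fdr_replication = fdr_replication,
                 r2_threshold = r2_threshold, clump_group = clump_group,
                 covariates = covariates, transform = transform,
                 seed = as.integer(seed)),
            class = "gxm_pipeline_config")
}

#' Run the full promoter G x M interaction analysis
#'
#' Orchestrates prep (promoter windows, triplet enumeration, QC), the
#' interaction scan, LD clumping, optional regulatory-peak enrichment and
#' the methylation-stratified characterisation of the retained pairs.
#' Inputs come either from the file paths in `config` or from an in-memory
#' `cohort` (a `gxm_cohort` or a list with the same elements). Stage row
#' counts are collected in the manifest; the run is deterministic given
#' config and inputs.
#'
#' @param config a [pipeline_config()] object.
#' @param cohort optional in-memory input bundle (overrides config paths).
#' @param peaks optional named list of `gxm_peaks` objects for enrichment.
#' @return list of class `gxm_result` with `triplets`, `scan`, `clump`,
#'   `enrichment` (or NULL), `stratified`, `manifest`.
#' @export
run_full_analysis <- function(config, cohort = NULL, peaks = NULL) {
  stopifnot(inherits(config, "gxm_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(cohort)) {
    for (f in c("vcf", "gtf", "meth", "expr", "probes", "pheno"))
      if (is.null(config[[f]])) stop("config lacks input path '", f, "'")
    cohort <- stage("load", {
      genotypes <- read_vcf_genotypes(config$vcf)
      transcripts <- read_gtf_transcripts(config$gtf)
      beta <- read_omics_matrix(config$meth, "methylation")
      probes <- utils::read.delim(config$probes, stringsAsFactors = FALSE)
      tpm <- read_omics_matrix(config$expr, "expression")
      list(genotypes = genotypes,
           methylation = methylation_matrix(
             beta[, probes$probe_id, drop = FALSE], probes),
           expression = expression_matrix(
             tpm[, transcripts$transcript_id, drop = FALSE], transcripts),
           annotation = transcripts,
           phenotypes = read_phenotypes(config$pheno))
    })
  }
  manifest <- list(config = unclass(config), stages = list())

  windows <- stage("prep", promoter_windows(cohort$annotation,
                                            config$upstream,
                                            config$downstream))
  triplets <- stage("prep", enumerate_triplets(windows, cohort$genotypes,
                                               cohort$methylation))
  manifest$stages$enumerated <- nrow(triplets)
  triplets <- stage("qc", apply_qc(triplets, cohort$genotypes,
                                   cohort$expression,
                                   config$maf_min, config$tpm_median_min))
  manifest$stages$after_qc <- nrow(triplets)

  scan <- stage("scan", run_scan(triplets, cohort$genotypes,
                                 cohort$methylation, cohort$expression,
                                 cohort$phenotypes,
                                 covariates = config$covariates,
                                 transform = config$transform,
                                 fdr = config$fdr_primary))
  manifest$stages$tested <- sum(!scan$degenerate)
  manifest$stages$degenerate <- sum(scan$degenerate)
  manifest$stages$significant <- sum(scan$significant)

  sig <- scan[scan$significant, , drop = FALSE]
  clump <- if (nrow(sig))
    stage("clump", clump_pairs(sig, cohort$genotypes,
                               r2_threshold = config$r2_threshold,
                               group = config$clump_group))
  else list(retained = sig, removed = NULL,
            r2_threshold = config$r2_threshold, group = config$clump_group)
  manifest$stages$clumped <- nrow(clump$retained)

  enrichment <- NULL
  if (!is.null(peaks) && nrow(sig)) {
    enrichment <- stage("enrich", {
      v <- cohort$genotypes$variants
      bg <- data.frame(feature_id = unique(scan$variant_id),
                       stringsAsFactors = FALSE)
      bg$chrom <- v$chrom[match(bg$feature_id, v$variant_id)]
      bg$pos <- v$pos[match(bg$feature_id, v$variant_id)]
      sf <- bg[bg$feature_id %in% sig$variant_id, , drop = FALSE]
      do.call(rbind, lapply(names(peaks), function(nm)
        peak_overlap_enrichment(sf, bg, peaks[[nm]], marker = nm)))
    })
  }

  stratified <- NULL
  if (nrow(clump$retained)) {
    stratified <- stage("stratify", {
      samples <- .common_samples(cohort$genotypes, cohort$methylation,
                                 cohort$expression, cohort$phenotypes)
      Y <- transform_expression(cohort$expression$tpm[samples, , drop = FALSE],
                                config$transform)
      out <- lapply(seq_len(nrow(clump$retained)), function(i) {
        r <- clump$retained[i, ]
        mvals <- cohort$methylation$beta[samples, r$probe_id]
        labels <- tryCatch(split_by_methylation(mvals),
                           error = function(e) NULL)
        if (is.null(labels)) return(NULL)
        eff <- stratified_effect(Y[, r$transcript_id],
                                 cohort$genotypes$dosage[samples, r$variant_id],
                                 labels, m = mvals)
        cbind(r[rep(1, nrow(eff)), c("transcript_id", "variant_id",
                                     "probe_id")], eff,
              row.names = NULL)
      })
      out <- out[!vapply(out, is.null, logical(1))]
      if (length(out)) do.call(rbind, out) else NULL
    })
  }

  result <- structure(list(triplets = triplets, scan = scan, clump = clump,
                           enrichment = enrichment, stratified = stratified,
                           manifest = manifest),
                      class = "gxm_result")
  if (!is.null(config$out_dir)) .write_result(result, config$out_dir)
  result
}

.write_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$scan, "scan.tsv")
  wt(result$clump$retained, "clumped.tsv")
  if (!is.null(result$enrichment)) wt(result$enrichment, "enrich.tsv")
  if (!is.null(result$stratified)) wt(result$stratified, "stratified.tsv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}

#' @export
print.gxm_result <- function(x, ...) {
  s <- x$manifest$stages
  cat("<gxm_result>\n",
      "  triplets enumerated: ", s$enumerated, "\n",
      "  after QC:            ", s$after_qc, "\n",
      "  tested (non-degen.): ", s$tested, "\n",
      "  significant:         ", s$significant, "\n",
      "  retained after clump:", s$clumped, "\n", sep = "")
  invisible(x)
}
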