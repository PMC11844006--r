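#' Build strand-aware promoter windows around transcription start sites
#'
#' The promoter is the 2,000 bp upstream to 200 bp downstream of the TSS in
#' the direction of transcription: `[TSS - upstream, TSS + downstream]` on
#' the `+` strand, `[TSS - downstream, TSS + upstream]` on the `-` strand
#' (1-based, closed, boundary inclusive), clipped at position 1.
#'
#' @param transcripts data.frame with `transcript_id`, `chrom`, `strand`,
#'   `tss` (e.g. from [read_gtf_transcripts()]).
#' @param upstream,downstream window extent in bp (defaults 2000 / 200).
#' @return data.frame with `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
promoter_windows <- function(transcripts, upstream = 2000, downstream = 200) {
  stopifnot(all(c("transcript_id", "chrom", "strand", "tss") %in%
                  names(transcripts)))
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("every transcript needs strand '+' or '-'")
  plus <- transcripts$strand == "+"
  start <- ifelse(plus, transcripts$tss - upstream,
                  transcripts$tss - downstream)
  end <- ifelse(plus, transcripts$tss + downstream,
                transcripts$tss + upstream)
  data.frame(
    transcript_id = as.character(transcripts$transcript_id),
    chrom = transcripts$chrom,
    start = pmax(1, start),
    end = end,
    strand = transcripts$strand,
    tss = transcripts$tss,
    stringsAsFactors = FALSE
  )
}

#' Signed distance of a position from a transcript's TSS
#'
#' Positive downstream of the TSS in the direction of transcription,
#' negative upstream, 0 at the TSS itself.
#'
#' @param pos 1-based feature position(s).
#' @param tss 1-based TSS position(s).
#' @param strand `"+"` or `"-"` (recycled).
#' @return integer vector of signed base-pair distances.
#' @export
distance_to_tss <- function(pos, tss, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  n <- max(length(pos), length(tss), length(strand))
  pos <- rep_len(pos, n); tss <- rep_len(tss, n)
  strand <- rep_len(strand, n)
  ifelse(strand == "+", pos - tss, tss - pos)
}

#' Enumerate (transcript, SNP, probe) triplets within promoter windows
#'
#' For each transcript, the full cross product of its in-window SNPs and
#' in-window probes (closed-interval containment, so features exactly on a
#' window boundary are included). A SNP inside the promoters of two
#' overlapping transcripts appears in both transcripts' triplets.
#'
#' @param windows promoter windows from [promoter_windows()].
#' @param genotypes a [genotype_matrix()] object.
#' @param methylation a [methylation_matrix()] object.
#' @return data.frame with `transcript_id`, `variant_id`, `probe_id` and the
#'   signed TSS distances `snp_dist`, `probe_dist`.
#' @export
enumerate_triplets <- function(windows, genotypes, methylation) {
  v <- genotypes$variants
  p <- methylation$probes
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    vi <- which(v$chrom == w$chrom & v$pos >= w$start & v$pos <= w$end)
    pi <- which(p$chrom == w$chrom & p$pos >= w$start & p$pos <= w$end)
    if (!length(vi) || !length(pi)) next
    grid <- expand.grid(vi = vi, pi = pi, KEEP.OUT.ATTRS = FALSE)
    out[[i]] <- data.frame(
      transcript_id = w$transcript_id,
      variant_id = v$variant_id[grid$vi],
      probe_id = p$probe_id[grid$pi],
      snp_dist = distance_to_tss(v$pos[grid$vi], w$tss, w$strand),
      probe_dist = distance_to_tss(p$pos[grid$pi], w$tss, w$strand),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(transcript_id = character(), variant_id = character(),
                      probe_id = character(), snp_dist = integer(),
                      probe_dist = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (anyDuplicated(res[, c("transcript_id", "variant_id", "probe_id")]))
    stop("duplicate triplets produced; check feature metadata for duplicates")
  res
}

#' Apply the scan's quality-control filters to a triplet set
#'
#' Drops triplets whose SNP has minor-allele frequency <= `maf_min`
#' (strictly greater required), whose SNP is monomorphic in the cohort, or
#' whose transcript has median TPM <= `tpm_median_min` across all samples
#' (strictly greater required). Per-filter drop-out counts are reported via
#' `message()`.
#'
#' @param triplets data.frame from [enumerate_triplets()].
#' @param genotypes a [genotype_matrix()] object (analysis cohort).
#' @param expression an [expression_matrix()] object (analysis cohort).
#' @param maf_min MAF threshold (default 0.05, strict).
#' @param tpm_median_min median-TPM threshold (default 0.1, strict).
#' @return the filtered triplet data.frame.
#' @export
apply_qc <- function(triplets, genotypes, expression,
                     maf_min = 0.05, tpm_median_min = 0.1) {
  if (!nrow(triplets)) return(triplets)
  maf <- genotypes$variants$maf[match(triplets$variant_id,
                                      genotypes$variants$variant_id)]
  if (anyNA(maf)) stop("triplet variants missing from genotype matrix")
  med_tpm <- apply(expression$tpm, 2, stats::median, na.rm = TRUE)
  med <- med_tpm[match(triplets$transcript_id,
                       colnames(expression$tpm))]
  if (anyNA(med)) stop("triplet transcripts missing from expression matrix")
  poly <- maf > 0                       # monomorphic SNPs carry MAF 0
  keep_maf <- maf > maf_min
  keep_tpm <- med > tpm_median_min
  message("apply_qc: dropped ", sum(!poly), " monomorphic, ",
          sum(poly & !keep_maf), " MAF<=", maf_min, ", ",
          sum(poly & keep_maf & !keep_tpm), " median TPM<=", tpm_median_min,
          " of ", nrow(triplets), " triplets")
  out <- triplets[poly & keep_maf & keep_tpm, , drop = FALSE]
  rownames(out) <- NULL
  out
}
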