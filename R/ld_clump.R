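#' Squared dosage correlation (LD r-squared) between two variants
#'
#' Squared Pearson correlation of minor-allele dosage vectors over
#' pairwise-complete samples. Invariant to allele flips (`g -> 2 - g`).
#'
#' @param g1,g2 dosage vectors over the same samples.
#' @return r-squared in \[0, 1\], or `NA` when either vector is monomorphic
#'   (correlation undefined).
#' @export
genotype_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(g1) < 2 || stats::var(g1) == 0 || stats::var(g2) == 0)
    return(NA_real_)
  stats::cor(g1, g2)^2
}

#' Greedy LD clumping of significant interaction pairs
#'
#' Within each clumping group, pairs are processed in order of ascending
#' p-value (ties broken by variant chromosome, position, then probe id);
#' the best remaining pair becomes an index and every remaining pair whose
#' SNP has `r^2 >=` `r2_threshold` with the index SNP is removed and mapped
#' to it. Retained pairs within a group are therefore mutually below the
#' threshold, and each carries the lowest p of its clump.
#'
#' @param significant a scan table (rows to clump, typically the
#'   `significant` subset of [run_scan()] output).
#' @param genotypes a [genotype_matrix()] object providing dosages for the
#'   r-squared computation (the analysis cohort by default; pass genotypes
#'   read from a reference-panel VCF to mimic panel-based clumping).
#' @param r2_threshold LD threshold in (0, 1\] (default 0.8).
#' @param group clumping group: `"transcript-probe"` (default; SNPs compete
#'   only within the same transcript and probe), `"transcript"`, or
#'   `"global"`.
#' @return list of class `gxm_clump` with `retained` (scan-table subset),
#'   `removed` (mapping removed pair -> retaining pair with the `r2` used),
#'   `r2_threshold`, `group`.
#' @export
clump_pairs <- function(significant, genotypes, r2_threshold = 0.8,
                        group = c("transcript-probe", "transcript", "global")) {
  group <- match.arg(group)
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]")
  if (!nrow(significant)) stop("no pairs to clump")
  v <- genotypes$variants
  gi <- match(significant$variant_id, v$variant_id)
  if (anyNA(gi)) stop("variants missing from genotype matrix")
  key <- switch(group,
    "transcript-probe" = paste(significant$transcript_id,
                               significant$probe_id, sep = "\r"),
    "transcript" = significant$transcript_id,
    "global" = rep("all", nrow(significant))
  )
  ord <- order(significant$p, v$chrom[gi], v$pos[gi], significant$probe_id)
  retained_idx <- integer(0)
  removed <- list()
  for (k in unique(key)) {
    cand <- ord[key[ord] == k]             # ascending p within group
    while (length(cand)) {
      idx <- cand[1]
      retained_idx <- c(retained_idx, idx)
      cand <- cand[-1]
      if (!length(cand)) break
      r2 <- vapply(cand, function(j)
        genotype_r2(genotypes$dosage[, gi[idx]], genotypes$dosage[, gi[j]]),
        numeric(1))
      hit <- !is.na(r2) & r2 >= r2_threshold
      if (any(hit))
        removed[[length(removed) + 1]] <- data.frame(
          removed_transcript = significant$transcript_id[cand[hit]],
          removed_variant = significant$variant_id[cand[hit]],
          removed_probe = significant$probe_id[cand[hit]],
          retained_variant = significant$variant_id[idx],
          retained_probe = significant$probe_id[idx],
          r2 = r2[hit],
          stringsAsFactors = FALSE)
      cand <- cand[!hit]
    }
  }
  retained_idx <- sort(retained_idx)
  removed <- if (length(removed)) do.call(rbind, removed)
             else data.frame(removed_transcript = character(),
                             removed_variant = character(),
                             removed_probe = character(),
                             retained_variant = character(),
                             retained_probe = character(),
                             r2 = numeric(), stringsAsFactors = FALSE)
  retained <- significant[retained_idx, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(retained = retained, removed = removed,
                 r2_threshold = r2_threshold, group = group),
            class = "gxm_clump")
}

#' @export
print.gxm_clump <- function(x, ...) {
  cat("<gxm_clump> ", nrow(x$retained), " retained / ",
      nrow(x$removed), " removed at r2 >= ", x$r2_threshold,
      " (group: ", x$group, ")\n", sep = "")
  invisible(x)
}
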