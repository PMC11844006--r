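#' Construct a genotype matrix object
#'
#' Holds per-sample minor-allele dosages (0/1/2, `NA` allowed) together with
#' variant metadata. Dosage counts the minor allele, so effect signs and the
#' MAF filter are comparable across sites regardless of which allele is REF.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids); entries in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`; one row per column of `dosage`. MAF and
#'   missingness are (re)computed from `dosage`.
#' @return An object of class `gxm_genotypes`: a list with elements `dosage`
#'   and `variants` (the latter gaining `maf` and `missing_frac` columns).
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  required <- c("variant_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols))
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " variants but metadata has ", nrow(variants))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage must carry sample ids (rownames) and variant ids (colnames)")
  if (!identical(colnames(dosage), as.character(variants$variant_id)))
    stop("dosage column order does not match variants$variant_id")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id in variant metadata")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  variants$variant_id <- as.character(variants$variant_id)
  variants$maf <- apply(dosage, 2, .dosage_maf)
  variants$missing_frac <- colMeans(is.na(dosage))
  structure(list(dosage = dosage, variants = variants), class = "gxm_genotypes")
}

# minor-allele frequency from a dosage vector, non-missing calls only
.dosage_maf <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Construct a methylation matrix object
#'
#' @param beta numeric matrix of beta values in \[0, 1\], samples in rows,
#'   probes in columns; dimnames required.
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos` (1-based).
#' @return An object of class `gxm_methylation`.
#' @export
methylation_matrix <- function(beta, probes) {
  stopifnot(is.matrix(beta), is.data.frame(probes))
  required <- c("probe_id", "chrom", "pos")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols))
    stop("probes table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (ncol(beta) != nrow(probes))
    stop("beta has ", ncol(beta), " probes but metadata has ", nrow(probes))
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must carry sample ids (rownames) and probe ids (colnames)")
  if (!identical(colnames(beta), as.character(probes$probe_id)))
    stop("beta column order does not match probes$probe_id")
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values outside [0, 1]: range ", rng[1], "..", rng[2])
  probes$probe_id <- as.character(probes$probe_id)
  structure(list(beta = beta, probes = probes), class = "gxm_methylation")
}

#' Construct an expression matrix object
#'
#' @param tpm numeric matrix of non-negative TPM values, samples in rows,
#'   transcripts in columns; dimnames required.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"` or `"-"`), `tss` (1-based).
#' @return An object of class `gxm_expression`.
#' @export
expression_matrix <- function(tpm, transcripts) {
  stopifnot(is.matrix(tpm), is.data.frame(transcripts))
  required <- c("transcript_id", "gene_id", "chrom", "strand", "tss")
  missing_cols <- setdiff(required, names(transcripts))
  if (length(missing_cols))
    stop("transcripts table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (ncol(tpm) != nrow(transcripts))
    stop("tpm has ", ncol(tpm), " transcripts but metadata has ", nrow(transcripts))
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("tpm must carry sample ids (rownames) and transcript ids (colnames)")
  if (!identical(colnames(tpm), as.character(transcripts$transcript_id)))
    stop("tpm column order does not match transcripts$transcript_id")
  if (anyDuplicated(transcripts$transcript_id)) stop("duplicate transcript_id")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("every transcript needs strand '+' or '-'")
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be >= 0")
  transcripts$transcript_id <- as.character(transcripts$transcript_id)
  structure(list(tpm = tpm, transcripts = transcripts), class = "gxm_expression")
}

#' @export
print.gxm_genotypes <- function(x, ...) {
  cat("<gxm_genotypes> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " variants; median MAF ",
      signif(stats::median(x$variants$maf, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.gxm_methylation <- function(x, ...) {
  cat("<gxm_methylation> ", nrow(x$beta), " samples x ", ncol(x$beta),
      " probes\n", sep = "")
  invisible(x)
}

#' @export
print.gxm_expression <- function(x, ...) {
  cat("<gxm_expression> ", nrow(x$tpm), " samples x ", ncol(x$tpm),
      " transcripts\n", sep = "")
  invisible(x)
}

#' Validate a phenotype table
#'
#' Requires one row per sample with at least `sample_id`, `sex` (0/1) and
#' `age`; `diagnosis` ("AD"/"CN"), `braak`, `cerad` and `apoe4` are optional.
#'
#' @param pheno data.frame.
#' @return The validated data.frame (invisibly unchanged apart from
#'   `sample_id` coerced to character).
#' @export
validate_phenotypes <- function(pheno) {
  stopifnot(is.data.frame(pheno))
  required <- c("sample_id", "sex", "age")
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  pheno$sample_id <- as.character(pheno$sample_id)
  if (anyDuplicated(pheno$sample_id)) stop("duplicate sample_id in phenotypes")
  if (!all(pheno$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if ("diagnosis" %in% names(pheno) &&
      !all(pheno$diagnosis %in% c("AD", "CN")))
    stop("diagnosis must be 'AD' or 'CN'")
  pheno
}

# shared-sample intersection across containers, preserving first object's order
.common_samples <- function(...) {
  ids <- lapply(list(...), function(x) {
    if (inherits(x, "gxm_genotypes")) rownames(x$dosage)
    else if (inherits(x, "gxm_methylation")) rownames(x$beta)
    else if (inherits(x, "gxm_expression")) rownames(x$tpm)
    else if (is.data.frame(x)) as.character(x$sample_id)
    else stop("unsupported object in sample intersection")
  })
  shared <- Reduce(intersect, ids)
  if (!length(shared)) stop("no samples shared across inputs")
  dropped <- sum(lengths(ids)) - length(ids) * length(shared)
  if (dropped > 0)
    message("sample intersection: ", length(shared), " shared samples kept")
  shared
}
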