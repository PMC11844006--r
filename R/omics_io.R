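#' Read genotypes from a VCF into minor-allele dosages
#'
#' Parses GT fields of a biallelic VCF: `0/0` -> 0, `0/1`/`1|0` -> 1,
#' `1/1` -> 2 on the ALT-count scale, `./.` -> missing. Sites whose ALT
#' frequency (computed from non-missing calls) exceeds 0.5 are flipped to
#' minor-allele dosage (`d -> 2 - d`) so that dosage always counts the minor
#' allele. Multi-allelic records are skipped with a message.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional character vector restricting (and ordering) the
#'   sample set; ids absent from the file are an error.
#' @return A [genotype_matrix()] object.
#' @export
read_vcf_genotypes <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    message("read_vcf_genotypes: skipped ", sum(multi), " multi-allelic record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")  # variants x samples
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!is.null(samples)) {
    absent <- setdiff(samples, colnames(gt))
    if (length(absent))
      stop("samples not present in VCF: ", paste(absent, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  dosage <- .gt_to_alt_count(gt)           # variants x samples, ALT count
  alt_freq <- rowMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  dosage[flip, ] <- 2 - dosage[flip, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(
    variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, flipped = flip,
    stringsAsFactors = FALSE
  )
  dm <- t(dosage)
  colnames(dm) <- variants$variant_id
  genotype_matrix(dm, variants)
}

# GT string matrix -> numeric ALT allele counts (NA for missing)
.gt_to_alt_count <- function(gt) {
  out <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
             "1/1" = 2, "1|1" = 2)
  idx <- match(gt, names(known))
  out[] <- known[idx]
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' Dosages are emitted as unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`)
#' counting the stored (minor) allele as ALT.
#'
#' @param geno a [genotype_matrix()] object.
#' @param path output file.
#' @export
write_vcf_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "gxm_genotypes"))
  v <- geno$variants
  samples <- rownames(geno$dosage)
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gxmscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    d <- geno$dosage[, i]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1])
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read transcript records from a GTF file
#'
#' Keeps `transcript` features; the TSS is the feature start on the `+`
#' strand and the feature end on the `-` strand (GTF intervals are 1-based,
#' closed). Strand-less records are dropped with a message; duplicated
#' transcript ids are an error.
#'
#' @param path GTF file (Ensembl dialect).
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tss`, `start`, `end`.
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "transcript", , drop = FALSE]
  if (!nrow(df)) stop("no transcript features in ", path)
  no_strand <- !(as.character(df$strand) %in% c("+", "-"))
  if (any(no_strand)) {
    message("read_gtf_transcripts: dropped ", sum(no_strand),
            " record(s) without strand")
    df <- df[!no_strand, , drop = FALSE]
  }
  if (anyDuplicated(df$transcript_id))
    stop("duplicate transcript_id in GTF: ",
         paste(unique(df$transcript_id[duplicated(df$transcript_id)]),
               collapse = ", "))
  strand <- as.character(df$strand)
  data.frame(
    transcript_id = as.character(df$transcript_id),
    gene_id = as.character(df$gene_id),
    chrom = as.character(df$seqnames),
    strand = strand,
    tss = ifelse(strand == "+", df$start, df$end),
    start = df$start, end = df$end,
    stringsAsFactors = FALSE
  )
}

#' Write transcript records as GTF
#'
#' @param transcripts data.frame as returned by [read_gtf_transcripts()].
#' @param path output file.
#' @export
write_gtf_transcripts <- function(transcripts, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   transcripts$gene_id, transcripts$transcript_id)
  lines <- paste(transcripts$chrom, "gxmscan", "transcript",
                 transcripts$start, transcripts$end, ".",
                 transcripts$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' Expects features in rows (first column = feature id) and samples in the
#' remaining columns; returns the transposed samples-by-features matrix the
#' scan operates on. Values are validated by kind: methylation betas must be
#' in \[0, 1\], expression TPM must be non-negative.
#'
#' @param path TSV file.
#' @param kind `"methylation"` or `"expression"`.
#' @return numeric matrix, samples in rows, features in columns.
#' @export
read_omics_matrix <- function(path, kind = c("methylation", "expression")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  feat <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop("non-numeric cell at feature '", feat[bad[1]], "', sample '",
         colnames(m)[bad[2]], "' in ", path)
  }
  rownames(m) <- feat
  m <- t(m)  # samples x features
  if (kind == "methylation") {
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop("methylation beta values outside [0, 1] in ", path)
  } else {
    if (any(m < 0, na.rm = TRUE))
      stop("negative TPM values in ", path)
  }
  m
}

#' Write a samples-by-features matrix as a feature-by-sample TSV
#'
#' @param m numeric matrix, samples in rows, features in columns.
#' @param path output file.
#' @param feature_col name for the first (feature id) column.
#' @param digits decimal digits written (round-trip precision of the file).
#' @export
write_omics_matrix <- function(m, path, feature_col = "feature_id",
                               digits = 10) {
  fm <- t(m)  # features x samples
  df <- data.frame(id = rownames(fm),
                   signif(fm, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' @param path TSV with columns `sample_id`, `sex` (0/1), `age`, optionally
#'   `diagnosis`, `braak`, `cerad`, `apoe4`.
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path) {
  validate_phenotypes(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read regulatory peaks from a BED file
#'
#' BED intervals are 0-based, half-open; they are stored as-is and the
#' containment test [positions_in_peaks()] converts on the fly (a 1-based
#' position `p` is inside `(start, end]`). Lines with `start >= end` are
#' dropped with a message.
#'
#' @param path BED3+ file.
#' @return data.frame of class `gxm_peaks` with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @export
read_bed_peaks <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  peaks <- data.frame(chrom = as.character(df[[1]]),
                      start = as.integer(df[[2]]),
                      end = as.integer(df[[3]]),
                      stringsAsFactors = FALSE)
  bad <- peaks$start >= peaks$end
  if (any(bad)) {
    message("read_bed_peaks: dropped ", sum(bad),
            " interval(s) with start >= end")
    peaks <- peaks[!bad, , drop = FALSE]
  }
  class(peaks) <- c("gxm_peaks", "data.frame")
  peaks
}

#' Test 1-based positions for containment in a peak set
#'
#' @param chrom,pos parallel vectors of chromosome and 1-based position.
#' @param peaks a `gxm_peaks` object (0-based half-open intervals).
#' @return logical vector: is each position inside any peak?
#' @export
positions_in_peaks <- function(chrom, pos, peaks) {
  stopifnot(length(chrom) == length(pos))
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    i <- which(chrom == ch)
    if (!nrow(p)) next
    out[i] <- vapply(pos[i], function(x) any(p$start < x & x <= p$end),
                     logical(1))
  }
  out
}
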