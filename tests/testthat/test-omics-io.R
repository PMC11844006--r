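# hand-written VCF used across the GT-parsing tests: 4 samples;
# site1: ordinary biallelic; site2: ALT is the major allele (freq 0.75);
# site3: multi-allelic (must be skipped); site4: one missing call
vcf_lines <- c(
  "##fileformat=VCFv4.2",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
  paste(c("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/0", "0|1"), collapse = "\t"),
  paste(c("chr1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1|1", "1/1", "0/1", "1/1"), collapse = "\t"),
  paste(c("chr1", "300", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "0/0", "1/2"), collapse = "\t"),
  paste(c("chr1", "400", "rs4", "T", "C", ".", "PASS", ".", "GT",
          "./.", "0/1", "0/0", "0/1"), collapse = "\t")
)

test_that("VCF GT parsing follows the minor-allele dosage convention", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  expect_message(geno <- read_vcf_genotypes(f), "multi-allelic")
  expect_equal(geno$variants$variant_id, c("rs1", "rs2", "rs4"))
  # rs1: ALT minor, het calls of either phase/order give dosage 1
  expect_equal(unname(geno$dosage[, "rs1"]), c(0, 1, 1, 1))
  # rs2: ALT frequency 7/8 > 0.5 -> flipped; "1|1" becomes dosage 0
  expect_true(geno$variants$flipped[2])
  expect_equal(unname(geno$dosage[, "rs2"]), c(0, 0, 1, 0))
  # rs4: missing call excluded from the MAF denominator: 2/(2*3)
  expect_equal(unname(geno$dosage[, "rs4"]), c(NA, 1, 0, 1))
  expect_equal(geno$variants$maf[3], 2 / 6)
})

test_that("VCF MAF equals brute-force allele counting on the GT strings", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  geno <- suppressMessages(read_vcf_genotypes(f))
  for (row in c(4, 5, 7)) {  # the biallelic body lines
    gts <- strsplit(vcf_lines[row], "\t")[[1]][10:13]
    alleles <- unlist(strsplit(gts, "[/|]"))
    alleles <- alleles[alleles != "."]
    f_alt <- mean(alleles == "1")
    id <- strsplit(vcf_lines[row], "\t")[[1]][3]
    expect_equal(geno$variants$maf[geno$variants$variant_id == id],
                 min(f_alt, 1 - f_alt))
  }
})

test_that("requesting unknown samples from a VCF is an error naming them", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  expect_error(suppressMessages(read_vcf_genotypes(f, c("s1", "nope"))),
               "nope")
})

test_that("VCF write/read round-trips dosages and metadata", {
  coh <- simulate_cohort(sim_config(n_samples = 30, n_transcripts = 4,
                                    maf_range = c(0.1, 0.4), seed = 11))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_genotypes(coh$genotypes, f)
  back <- read_vcf_genotypes(f)
  expect_equal(unname(back$dosage),
               unname(coh$genotypes$dosage[, back$variants$variant_id]))
  expect_equal(back$variants$pos,
               coh$genotypes$variants$pos[
                 match(back$variants$variant_id,
                       coh$genotypes$variants$variant_id)])
})

test_that("GTF transcripts get strand-aware TSS and duplicates are rejected", {
  f <- withr::local_tempfile(fileext = ".gtf")
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                   chrom = "chr2", strand = c("+", "-"),
                   tss = c(1000, 5000), start = c(1000, 1000),
                   end = c(5000, 5000), stringsAsFactors = FALSE)
  write_gtf_transcripts(tx, f)
  got <- read_gtf_transcripts(f)
  expect_equal(got$tss[got$transcript_id == "t1"], 1000)  # + strand: start
  expect_equal(got$tss[got$transcript_id == "t2"], 5000)  # - strand: end
  # a strand-less record is dropped with a message
  writeLines(c(readLines(f),
               "chr2\tx\ttranscript\t1\t10\t.\t.\t.\tgene_id \"g3\"; transcript_id \"t3\";"), f)
  expect_message(got2 <- read_gtf_transcripts(f), "without strand")
  expect_equal(nrow(got2), 2)
  # duplicated transcript_id is an error
  writeLines(c(readLines(f)[1:2], readLines(f)[1:2]), f)
  expect_error(read_gtf_transcripts(f), "duplicate transcript_id")
})

test_that("TSV matrices round-trip and are validated by kind", {
  m <- matrix(runif(12), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("cg", 1:3)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(m, f, feature_col = "probe_id")
  back <- read_omics_matrix(f, "methylation")
  expect_equal(back, m, tolerance = 1e-9)

  bad <- m; bad[2, 2] <- 1.5
  write_omics_matrix(bad, f)
  expect_error(read_omics_matrix(f, "methylation"), "\\[0, 1\\]")

  tpm <- m * 100; tpm[1, 1] <- -1
  write_omics_matrix(tpm, f)
  expect_error(read_omics_matrix(f, "expression"), "negative TPM")

  writeLines(c("id\ts1\ts2", "tx1\t1.0\toops"), f)
  expect_error(read_omics_matrix(f, "expression"), "non-numeric")
})

test_that("BED intervals keep the 0-based half-open convention", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500\t400"), f)
  expect_message(peaks <- read_bed_peaks(f), "start >= end")
  expect_equal(nrow(peaks), 1)
  # covers 1-based 101..200: 100 out, 101 in, 150 in, 200 in, 201 out
  expect_equal(
    positions_in_peaks(rep("chr1", 5), c(100, 101, 150, 200, 201), peaks),
    c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_false(positions_in_peaks("chr2", 150, peaks))
})

test_that("phenotype tables are validated", {
  ph <- data.frame(sample_id = c("a", "b"), sex = c(0, 1), age = c(70, 80),
                   diagnosis = c("AD", "CN"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(ph, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_phenotypes(f)$diagnosis, c("AD", "CN"))
  expect_error(validate_phenotypes(ph[c(1, 1), ]), "duplicate")
  ph$sex <- c(1, 2)
  expect_error(validate_phenotypes(ph), "sex")
})
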