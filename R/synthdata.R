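#' Configuration for the synthetic multi-omics cohort generator
#'
#' The generator emulates the statistical structure a promoter G x M
#' interaction scan assumes: SNPs in Hardy-Weinberg proportions with AR(1)
#' linkage disequilibrium within a promoter, beta-distributed CpG probe
#' values, and log2-scale transcript expression following
#' `y = b0 + beta_g G + beta_m M + beta_gm G*M + beta_sex sex + beta_age (age - 75) + e`
#' with `e ~ N(0, noise_sd^2)` and TPM = 2^y.
#'
#' @param n_samples number of samples (>= 10).
#' @param n_transcripts number of transcripts (one promoter each).
#' @param snps_per_promoter,probes_per_promoter features per promoter window.
#' @param maf_range range the per-variant minor-allele frequency is drawn
#'   from, within (0, 0.5].
#' @param ld_rho AR(1) correlation of the latent Gaussian allele variables
#'   between adjacent SNPs of one promoter, in \[0, 1).
#' @param frac_interaction fraction of (transcript, SNP, probe) triplets
#'   carrying a true interaction effect `beta_gm`.
#' @param beta_g,beta_m main effects (log2 units per dosage / per beta unit),
#'   attached to each transcript's first SNP and first probe.
#' @param beta_gm interaction effect (log2 units per dosage x beta product).
#' @param beta_sex,beta_age covariate effects (age is centred at 75 years).
#' @param noise_sd residual SD on the log2 scale (> 0).
#' @param beta0 baseline log2 expression (default 8, i.e. TPM ~ 256).
#' @param meth_shape1,meth_shape2 Beta distribution shapes for probe values;
#'   the (0.5, 0.5) default gives the bimodal low/high mix typical of
#'   array-wide CpG beta values.
#' @param age_range range ages are drawn from uniformly (years).
#' @param meqtl_rho optional meQTL coupling: logit-scale shift of each
#'   promoter's probes by its lead SNP dosage (0 = methylation independent
#'   of genotype, the default).
#' @param seed integer master seed; identical configs give byte-identical
#'   cohorts.
#' @return validated list of class `gxm_sim_config`.
#' @export
sim_config <- function(n_samples = 360, n_transcripts = 500,
                       snps_per_promoter = 2, probes_per_promoter = 2,
                       maf_range = c(0.05, 0.5), ld_rho = 0.3,
                       frac_interaction = 0.05,
                       beta_g = 0.5, beta_m = 0.5, beta_gm = 1,
                       beta_sex = 0.25, beta_age = 0.02,
                       noise_sd = 1, beta0 = 8,
                       meth_shape1 = 0.5, meth_shape2 = 0.5,
                       age_range = c(65, 90), meqtl_rho = 0, seed = 1) {
  cfg <- list(n_samples = n_samples, n_transcripts = n_transcripts,
              snps_per_promoter = snps_per_promoter,
              probes_per_promoter = probes_per_promoter,
              maf_range = maf_range, ld_rho = ld_rho,
              frac_interaction = frac_interaction,
              beta_g = beta_g, beta_m = beta_m, beta_gm = beta_gm,
              beta_sex = beta_sex, beta_age = beta_age,
              noise_sd = noise_sd, beta0 = beta0,
              meth_shape1 = meth_shape1, meth_shape2 = meth_shape2,
              age_range = age_range, meqtl_rho = meqtl_rho,
              seed = as.integer(seed))
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (n_transcripts < 1 || snps_per_promoter < 1 || probes_per_promoter < 1)
    stop("need at least one transcript, SNP and probe per promoter")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (frac_interaction < 0 || frac_interaction > 1)
    stop("frac_interaction must be in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(cfg, class = "gxm_sim_config")
}

# evaluate expr under a private, fully specified RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# transcript scaffold: evenly spaced 1 kb transcripts on chr1, alternating
# strand, TSS far enough from the origin that windows never clip
.sim_annotation <- function(config) {
  n <- config$n_transcripts
  i <- seq_len(n)
  strand <- ifelse(i %% 2 == 1, "+", "-")
  tss <- 10000 + (i - 1) * 20000
  data.frame(
    transcript_id = sprintf("TX%05d", i),
    gene_id = sprintf("GENE%05d", i),
    chrom = "chr1",
    strand = strand,
    tss = tss,
    start = ifelse(strand == "+", tss, tss - 999L),
    end = ifelse(strand == "+", tss + 999L, tss),
    stringsAsFactors = FALSE
  )
}

#' Simulate a matched multi-omics cohort with planted interaction effects
#'
#' Draws genotypes, methylation, phenotypes and expression under the
#' generative model described in [sim_config()], and records every planted
#' coefficient per (transcript, SNP, probe) triplet in a truth table. Main
#' effects `beta_g`/`beta_m` act through each transcript's first SNP and
#' first probe; interaction effects act through a fixed-size random subset
#' of triplets (`round(frac_interaction * n_triplets)` of them).
#'
#' @param config a [sim_config()] object.
#' @return list of class `gxm_cohort` with elements `genotypes`
#'   ([genotype_matrix()]), `methylation` ([methylation_matrix()]),
#'   `expression` ([expression_matrix()]), `phenotypes` (data.frame),
#'   `annotation` (transcript data.frame) and `truth` (data.frame with one
#'   row per triplet: ids plus `true_beta_g`, `true_beta_m`, `true_beta_gm`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "gxm_sim_config"))
  .with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  n <- config$n_samples
  ann <- .sim_annotation(config)
  nt <- nrow(ann)
  ns <- config$snps_per_promoter
  np <- config$probes_per_promoter
  sample_ids <- sprintf("S%04d", seq_len(n))

  windows <- promoter_windows(ann)

  # --- feature placement inside promoter windows ---
  snp_pos <- matrix(0L, nt, ns)
  probe_pos <- matrix(0L, nt, np)
  for (t in seq_len(nt)) {
    w <- windows$start[t]:windows$end[t]
    snp_pos[t, ] <- sort(sample(w, ns))
    probe_pos[t, ] <- sort(sample(w, np))
  }

  # --- genotypes: Gaussian copula, AR(1) within promoter, HWE marginals ---
  # one MAF per promoter LD block: tightly linked variants share allele
  # frequency (perfect LD implies identical MAF), so ld_rho stays
  # interpretable as the block correlation
  maf <- matrix(stats::runif(nt, config$maf_range[1], config$maf_range[2]),
                nt, ns)
  if (any(2 * n * maf < 1))
    warning("expected minor-allele count < 1 for some variants; ",
            "they may be monomorphic in the cohort")
  rho <- config$ld_rho
  dosage <- matrix(0, n, nt * ns)
  for (t in seq_len(nt)) {
    thr <- stats::qnorm(maf[t, ])
    g <- matrix(0, n, ns)
    for (copy in 1:2) {
      z <- matrix(stats::rnorm(n * ns), n, ns)
      if (ns > 1 && rho > 0)
        for (j in 2:ns) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      g <- g + sweep(z, 2, thr, "<")
    }
    dosage[, (t - 1) * ns + seq_len(ns)] <- g
  }
  variant_id <- as.vector(t(outer(seq_len(nt), seq_len(ns),
                                  function(t, j) sprintf("var%05d_%d", t, j))))
  variants <- data.frame(
    variant_id = variant_id,
    chrom = rep(ann$chrom, each = ns),
    pos = as.integer(t(snp_pos)),
    ref = "A", alt = "G",
    transcript_id = rep(ann$transcript_id, each = ns),
    stringsAsFactors = FALSE
  )
  dimnames(dosage) <- list(sample_ids, variant_id)
  genotypes <- genotype_matrix(dosage, variants)

  # --- methylation: Beta marginals, optional meQTL coupling ---
  beta <- matrix(stats::rbeta(n * nt * np, config$meth_shape1,
                              config$meth_shape2), n, nt * np)
  probe_id <- as.vector(t(outer(seq_len(nt), seq_len(np),
                                function(t, j) sprintf("cg%05d_%d", t, j))))
  if (config$meqtl_rho > 0) {
    for (t in seq_len(nt)) {
      g_lead <- dosage[, (t - 1) * ns + 1]
      shift <- config$meqtl_rho * (g_lead - mean(g_lead))
      cols <- (t - 1) * np + seq_len(np)
      b <- pmin(pmax(beta[, cols, drop = FALSE], 1e-6), 1 - 1e-6)
      beta[, cols] <- stats::plogis(stats::qlogis(b) + shift)
    }
  }
  probes <- data.frame(
    probe_id = probe_id,
    chrom = rep(ann$chrom, each = np),
    pos = as.integer(t(probe_pos)),
    transcript_id = rep(ann$transcript_id, each = np),
    stringsAsFactors = FALSE
  )
  dimnames(beta) <- list(sample_ids, probe_id)
  methylation <- methylation_matrix(beta, probes)

  # --- phenotypes ---
  sex <- stats::rbinom(n, 1, 0.5)
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
  cerad <- sample(1:4, n, replace = TRUE, prob = c(0.25, 0.25, 0.23, 0.27))
  diagnosis <- ifelse(cerad <= 3, "AD", "CN")
  braak <- sample(0:6, n, replace = TRUE)
  apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.64, 0.32, 0.04))
  phenotypes <- data.frame(sample_id = sample_ids, sex = sex, age = age,
                           diagnosis = diagnosis, braak = braak,
                           cerad = cerad, apoe4 = apoe4,
                           stringsAsFactors = FALSE)

  # --- truth table: triplet enumeration + planted effects ---
  ti <- rep(seq_len(nt), each = ns * np)
  si <- rep(rep(seq_len(ns), each = np), times = nt)
  pj <- rep(rep(seq_len(np), times = ns), times = nt)
  truth <- data.frame(
    transcript_id = ann$transcript_id[ti],
    variant_id = variant_id[(ti - 1) * ns + si],
    probe_id = probe_id[(ti - 1) * np + pj],
    stringsAsFactors = FALSE
  )
  n_triplets <- nrow(truth)
  truth$true_beta_g <- ifelse(
    truth$variant_id %in% variant_id[seq(1, nt * ns, by = ns)],
    config$beta_g, 0)
  truth$true_beta_m <- ifelse(
    truth$probe_id %in% probe_id[seq(1, nt * np, by = np)],
    config$beta_m, 0)
  truth$true_beta_gm <- 0
  n_int <- round(config$frac_interaction * n_triplets)
  planted <- if (n_int > 0) sample(n_triplets, n_int) else integer(0)
  truth$true_beta_gm[planted] <- config$beta_gm

  # --- expression: log2-linear model, TPM = 2^y ---
  age_c <- age - 75
  y <- matrix(config$beta0, n, nt)
  for (t in seq_len(nt)) {
    g_lead <- dosage[, (t - 1) * ns + 1]
    m_lead <- beta[, (t - 1) * np + 1]
    y[, t] <- y[, t] + config$beta_g * g_lead + config$beta_m * m_lead +
      config$beta_sex * sex + config$beta_age * age_c
  }
  if (length(planted)) {
    gi <- match(truth$variant_id[planted], variant_id)
    pi <- match(truth$probe_id[planted], probe_id)
    ti <- match(truth$transcript_id[planted], ann$transcript_id)
    for (k in seq_along(planted))
      y[, ti[k]] <- y[, ti[k]] +
        config$beta_gm * dosage[, gi[k]] * beta[, pi[k]]
  }
  y <- y + matrix(stats::rnorm(n * nt, 0, config$noise_sd), n, nt)
  tpm <- 2^y
  dimnames(tpm) <- list(sample_ids, ann$transcript_id)
  expression <- expression_matrix(tpm, ann[, c("transcript_id", "gene_id",
                                               "chrom", "strand", "tss")])

  structure(list(genotypes = genotypes, methylation = methylation,
                 expression = expression, phenotypes = phenotypes,
                 annotation = ann, truth = truth, config = config),
            class = "gxm_cohort")
}

#' Configuration of the packaged end-to-end demonstration fixture
#'
#' A small seeded cohort used by the test suite and the worked examples:
#' 50 transcripts, two SNPs per promoter in near-perfect LD (latent AR(1)
#' correlation 0.999, dosage r-squared ~ 0.95) plus one probe, and 10 of
#' the 100 triplets carrying a planted interaction of `beta_gm = 1`.
#' `noise_sd = 0.5` puts the planted interaction's noncentrality around 75
#' at n = 360, so recovery of all planted triplets is essentially certain,
#' while the LD twins let clumping demonstrably collapse duplicated
#' signals. MAF is drawn from (0.1, 0.5), clear of the 0.05 QC boundary.
#'
#' @param seed master seed (default 101).
#' @return a [sim_config()] object.
#' @export
fixture_cohort_config <- function(seed = 101) {
  sim_config(n_samples = 360, n_transcripts = 50, snps_per_promoter = 2,
             probes_per_promoter = 1, maf_range = c(0.1, 0.5),
             ld_rho = 0.999, frac_interaction = 0.1, beta_gm = 1,
             noise_sd = 0.5, seed = seed)
}

#' Simulate genotypes only
#'
#' Convenience wrapper drawing the full cohort (so results are identical to
#' [simulate_cohort()] under the same config) and returning its genotype
#' component: variants in Hardy-Weinberg proportions at their drawn MAF,
#' adjacent within-promoter variants correlated via the AR(1) Gaussian
#' copula, coordinates inside the promoter windows.
#'
#' @param config a [sim_config()] object.
#' @return a [genotype_matrix()] object.
#' @export
simulate_genotypes <- function(config) {
  simulate_cohort(config)$genotypes
}

#' @export
print.gxm_cohort <- function(x, ...) {
  cat("<gxm_cohort> ", nrow(x$phenotypes), " samples, ",
      nrow(x$annotation), " transcripts, ",
      nrow(x$truth), " triplets (",
      sum(x$truth$true_beta_gm != 0), " with planted interaction)\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits `genotypes.vcf` (GT fields, 1-based positions), `annotation.gtf`,
#' `methylation.tsv` / `expression.tsv` (features x samples), `probes.tsv`
#' (probe coordinates), `phenotypes.tsv` and `truth.tsv`.
#'
#' @param cohort a `gxm_cohort` object.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gxm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vcf_genotypes(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_gtf_transcripts(cohort$annotation, file.path(dir, "annotation.gtf"))
  write_omics_matrix(cohort$methylation$beta, file.path(dir, "methylation.tsv"),
                     feature_col = "probe_id")
  write_omics_matrix(cohort$expression$tpm, file.path(dir, "expression.tsv"),
                     feature_col = "transcript_id")
  utils::write.table(cohort$methylation$probes, file.path(dir, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
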