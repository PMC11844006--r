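test_that("methylation split is the optimal two-cluster threshold partition", {
  lab <- split_by_methylation(c(0.1, 0.1, 0.9, 0.9))
  expect_equal(as.character(lab), c("low", "low", "high", "high"))
  # exhaustive-search oracle over random inputs of varying size
  withr::with_seed(79, {
    for (i in 1:200) {
      x <- switch(sample(3, 1),
                  runif(sample(4:60, 1)),
                  rbeta(sample(4:60, 1), 0.5, 0.5),
                  rnorm(sample(4:60, 1), sample(0:1, 1)))
      if (var(x) == 0) next
      expect_identical(split_by_methylation(x), brute_split(x))
    }
  })
  # permuting samples permutes labels identically
  withr::with_seed(83, {
    x <- rbeta(20, 0.5, 0.5)
    perm <- sample(20)
    expect_identical(split_by_methylation(x)[perm],
                     split_by_methylation(x[perm]))
  })
  expect_error(split_by_methylation(rep(0.5, 10)), "constant")
  expect_error(split_by_methylation(c(0.1, 0.9)), "at least 4")
})

test_that("stratified genotype effects recover planted regime-specific slopes", {
  withr::with_seed(89, {
    n <- 300
    g <- rbinom(n, 2, 0.3)
    m <- rbeta(n, 0.5, 0.5)
    labels <- split_by_methylation(m)
    # slope -1 under low methylation, 0 under high
    y <- ifelse(labels == "low", -1 * g, 0) + rnorm(n, sd = 0.5)
    eff <- stratified_effect(y, g, labels, m = m)
    expect_equal(eff$group, c("low", "high"))
    expect_lt(eff$slope[1], -0.7)
    expect_lt(abs(eff$slope[2]), 0.2)
    expect_lt(eff$p[1], 1e-6)
    expect_lt(eff$mean_m[1], eff$mean_m[2])
    # per-group slopes equal the normal-equations solution
    for (k in 1:2) {
      i <- labels == eff$group[k]
      X <- cbind(1, g[i])
      beta <- solve(t(X) %*% X) %*% t(X) %*% y[i]
      expect_equal(eff$slope[k], beta[2], tolerance = 1e-10)
    }
  })
})

test_that("stratified effects handle exact-zero and monomorphic groups", {
  g <- rep(c(0, 1, 2), each = 4)
  y <- rep(c(1, -1), 6)             # balanced around 0 within every genotype
  labels <- factor(rep(c("low", "high"), each = 6),
                   levels = c("low", "high"))
  eff <- stratified_effect(y, g, labels)
  expect_equal(eff$slope, c(0, 0), tolerance = 1e-12)
  # monomorphic dosage in one group -> flagged, other group still fitted
  g2 <- c(rep(1, 6), 0, 0, 1, 1, 2, 2)
  eff2 <- stratified_effect(rnorm(12), g2, labels)
  expect_true(eff2$flagged[1])
  expect_false(eff2$flagged[2])
})

test_that("logistic DEG coefficients match an independent IRLS oracle", {
  withr::with_seed(97, {
    n <- 20
    tpm <- matrix(2^rnorm(n, 6), n, 1,
                  dimnames = list(paste0("s", 1:n), "tx1"))
    tr <- data.frame(transcript_id = "tx1", gene_id = "g1", chrom = "chr1",
                     strand = "+", tss = 1000, stringsAsFactors = FALSE)
    ph <- data.frame(sample_id = paste0("s", 1:n), sex = rbinom(n, 1, 0.5),
                     age = round(runif(n, 65, 90)),
                     diagnosis = rep(c("AD", "CN"), each = 10),
                     stringsAsFactors = FALSE)
    res <- case_control_deg(expression_matrix(tpm, tr), ph)
    # hand-rolled Newton/IRLS for logit(P(AD)) ~ expr + sex + age
    X <- cbind(1, log2(tpm[, 1] + 1), ph$sex, ph$age)
    yy <- as.numeric(ph$diagnosis == "AD")
    b <- rep(0, 4)
    for (it in 1:50) {
      eta <- as.vector(X %*% b)
      mu <- 1 / (1 + exp(-eta))
      W <- mu * (1 - mu)
      b_new <- b + solve(t(X) %*% (X * W), t(X) %*% (yy - mu))
      if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
      b <- b_new
    }
    expect_equal(res$estimate, b[2], tolerance = 1e-6)
    se_oracle <- sqrt(diag(solve(t(X) %*% (X * as.vector(mu * (1 - mu))))))[2]
    expect_equal(res$se, se_oracle, tolerance = 1e-4)
  })
})

test_that("logistic DEG is null-calibrated and label-antisymmetric", {
  coh <- simulate_cohort(sim_config(n_samples = 200, n_transcripts = 60,
                                    snps_per_promoter = 1,
                                    probes_per_promoter = 1, seed = 101))
  # diagnosis was drawn independently of expression -> null behaviour
  res <- case_control_deg(coh$expression, coh$phenotypes)
  ok <- !res$flagged
  expect_gt(ks.test(res$p[ok], "punif")$p.value, 0.001)
  expect_lt(abs(mean(res$estimate[ok])), 0.2)
  # swapping the diagnosis encoding flips every coefficient sign
  ph_sw <- coh$phenotypes
  ph_sw$diagnosis <- ifelse(ph_sw$diagnosis == "AD", "CN", "AD")
  res_sw <- case_control_deg(coh$expression, ph_sw)
  expect_equal(res_sw$estimate, -res$estimate, tolerance = 1e-8)
  # a single diagnosis class is a precondition failure
  ph_one <- coh$phenotypes; ph_one$diagnosis <- "AD"
  expect_error(case_control_deg(coh$expression, ph_one), "both diagnosis")
})

test_that("quartile DEG groups are strict and sized as expected", {
  n <- 40
  target <- as.numeric(1:n)
  tpm <- matrix(2^rnorm(n, 5), n, 2,
                dimnames = list(paste0("s", 1:n), c("tx1", "tx2")))
  tr <- data.frame(transcript_id = c("tx1", "tx2"), gene_id = c("g1", "g2"),
                   chrom = "chr1", strand = "+", tss = c(1e3, 2e3),
                   stringsAsFactors = FALSE)
  res <- quartile_deg(target, expression_matrix(tpm, tr))
  groups <- attr(res, "groups")
  expect_equal(length(groups$high), 10)
  expect_equal(length(groups$low), 10)
  # strict inequalities: values inside [Q1, Q3] are never assigned
  inside <- paste0("s", which(target >= groups$q1 & target <= groups$q3))
  expect_length(intersect(inside, c(groups$high, groups$low)), 0)
  # identical group means -> fold change 1 -> filtered out
  tpm_flat <- matrix(5, n, 1, dimnames = list(paste0("s", 1:n), "tx1"))
  res_flat <- quartile_deg(target, expression_matrix(tpm_flat, tr[1, ]))
  expect_equal(res_flat$fold_change, 1)
  expect_false(res_flat$significant)
})

test_that("quartile DEG recovers a planted four-fold change", {
  withr::with_seed(103, {
    n <- 200
    target <- 2^rnorm(n, 5)
    qs <- quantile(target, c(0.25, 0.75), type = 7)
    hi <- target > qs[2]
    # planted transcript: 4x higher mean TPM in the high group
    y2 <- 5 + 2 * hi + rnorm(n, sd = 0.5)
    tpm <- cbind(target = target, planted = 2^y2,
                 null1 = 2^rnorm(n, 5, 0.5), null2 = 2^rnorm(n, 5, 0.5))
    rownames(tpm) <- paste0("s", 1:n)
    tr <- data.frame(transcript_id = colnames(tpm), gene_id = colnames(tpm),
                     chrom = "chr1", strand = "+", tss = 1:4 * 1000,
                     stringsAsFactors = FALSE)
    res <- quartile_deg(target, expression_matrix(tpm, tr))
    planted <- res[res$transcript_id == "planted", ]
    expect_true(planted$significant)
    expect_gt(planted$fold_change, 2)
    expect_lt(planted$fold_change, 8)
    expect_equal(planted$direction, "high")
    expect_false(any(res$significant[res$transcript_id %in%
                                       c("null1", "null2")]))
  })
})

test_that("replication overlap counts pairs significant in both cohorts", {
  sc <- scan_stub("t1", paste0("v", 1:4), "cg1", c(1e-8, 1e-6, 0.2, 0.9))
  sc$q <- c(0.001, 0.01, 0.5, 0.9)
  # identical replication: everything replicates
  rep_same <- replication_overlap(sc, sc)
  expect_equal(rep_same$n_replicated, 2)
  expect_equal(rep_same$frac_pairs, 1)
  # disjoint significance: nothing replicates
  sc2 <- sc; sc2$q <- c(0.9, 0.8, 0.05, 0.02)
  expect_equal(replication_overlap(sc, sc2)$n_replicated, 0)
  # replication threshold is the looser FDR < 0.1
  sc3 <- sc; sc3$q <- c(0.09, 0.2, 0.9, 0.9)
  expect_equal(replication_overlap(sc, sc3)$n_replicated, 1)
  expect_warning(replication_overlap(sc, scan_stub("tX", "vX", "cgX", 0.5)),
                 "no shared")
})

test_that("replicated fraction grows with the planted effect size", {
  run_two_cohorts <- function(beta_gm, seed) {
    scans <- lapply(c(seed, seed + 1000), function(s) {
      nsamp <- if (s >= 1000) 120 else 360
      coh <- simulate_cohort(sim_config(
        n_samples = nsamp, n_transcripts = 150, snps_per_promoter = 1,
        probes_per_promoter = 1, maf_range = c(0.3, 0.3),
        frac_interaction = 0.2, beta_gm = beta_gm, seed = s))
      tri <- suppressMessages(apply_qc(
        enumerate_triplets(promoter_windows(coh$annotation),
                           coh$genotypes, coh$methylation),
        coh$genotypes, coh$expression))
      suppressMessages(run_scan(tri, coh$genotypes, coh$methylation,
                                coh$expression, coh$phenotypes))
    })
    replication_overlap(scans[[1]], scans[[2]])
  }
  weak <- run_two_cohorts(0.4, 7)
  strong <- run_two_cohorts(1.5, 7)
  expect_gt(strong$n_primary_sig, 0)
  expect_gt(strong$frac_pairs, 0)
  expect_lt(strong$frac_pairs, 1)
  expect_gt(strong$frac_pairs, ifelse(is.nan(weak$frac_pairs), 0,
                                      weak$frac_pairs))
})

test_that("-log10 p concordance behaves at its extremes", {
  sc <- scan_stub("t1", paste0("v", 1:5), "cg1", 10^-(1:5))
  expect_equal(neglogp_concordance(sc, sc), 1)
  anti <- sc; anti$p <- 10^-(5:1)
  expect_equal(neglogp_concordance(sc, anti), -1)
  expect_error(neglogp_concordance(sc[1:2, ], sc[1:2, ]), "fewer than 3")
})
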