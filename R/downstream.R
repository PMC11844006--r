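#' Split samples into low/high methylation groups
#'
#' Two-group clustering of one-dimensional methylation values, solved
#' exactly: values are sorted and every contiguous threshold split is
#' scored by within-cluster sum of squares; the minimising split is the
#' global two-cluster k-means optimum in one dimension and the procedure
#' is fully deterministic. Labels are mapped so `"low"` has the smaller
#' group mean.
#'
#' @param m_values numeric vector (>= 4 samples, non-constant).
#' @return factor with levels `c("low", "high")`, same order as the input.
#' @export
split_by_methylation <- function(m_values) {
  n <- length(m_values)
  if (n < 4) stop("need at least 4 samples to split")
  if (anyNA(m_values)) stop("missing methylation values")
  if (stats::var(m_values) == 0)
    stop("constant methylation values: no valid split")
  ord <- order(m_values)
  x <- m_values[ord]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  tot <- cs[n]; tot2 <- cs2[n]
  k <- seq_len(n - 1)
  # within-cluster SS for split after position k (low = x[1..k])
  wss <- (cs2[k] - cs[k]^2 / k) +
    ((tot2 - cs2[k]) - (tot - cs[k])^2 / (n - k))
  kbest <- which.min(wss)
  labels <- rep("high", n)
  labels[ord[seq_len(kbest)]] <- "low"
  factor(labels, levels = c("low", "high"))
}

#' Per-group genotype effect on expression, stratified by methylation
#'
#' Within each methylation group, ordinary least squares of transformed
#' expression on dosage (plus optional covariates), returning the genotype
#' slope, its standard error and Wald p-value per group. A group with
#' monomorphic dosage gets `NA` slope and is flagged.
#'
#' @param y transformed expression per sample.
#' @param g minor-allele dosage per sample (NA mean-imputed).
#' @param labels factor from [split_by_methylation()].
#' @param covars optional covariate matrix/data.frame.
#' @param m optional methylation values, used to report group means.
#' @return data.frame with one row per group: `group`, `n`, `slope`, `se`,
#'   `p`, `mean_m`, `flagged`.
#' @export
stratified_effect <- function(y, g, labels, covars = NULL, m = NULL) {
  stopifnot(length(y) == length(g), length(labels) == length(y))
  labels <- factor(labels, levels = c("low", "high"))
  g <- .impute_mean(g)
  out <- lapply(levels(labels), function(lv) {
    i <- which(labels == lv)
    mean_m <- if (is.null(m)) NA_real_ else mean(m[i])
    if (length(i) < 3 || length(unique(g[i])) < 2)
      return(data.frame(group = lv, n = length(i), slope = NA_real_,
                        se = NA_real_, p = NA_real_, mean_m = mean_m,
                        flagged = TRUE, stringsAsFactors = FALSE))
    X <- cbind("(Intercept)" = 1, g = g[i])
    if (!is.null(covars)) X <- cbind(X, as.matrix(covars)[i, , drop = FALSE])
    fit <- .ols_fit(X, y[i])
    if (fit$degenerate)
      return(data.frame(group = lv, n = length(i), slope = NA_real_,
                        se = NA_real_, p = NA_real_, mean_m = mean_m,
                        flagged = TRUE, stringsAsFactors = FALSE))
    tval <- fit$coefficients[["g"]] / fit$se[["g"]]
    data.frame(group = lv, n = length(i),
               slope = fit$coefficients[["g"]], se = fit$se[["g"]],
               p = 2 * stats::pt(abs(tval), fit$df_residual,
                                 lower.tail = FALSE),
               mean_m = mean_m, flagged = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!is.null(m) && all(!is.na(res$mean_m)) &&
      res$mean_m[1] >= res$mean_m[2])
    warning("'low' group does not have the smaller methylation mean; ",
            "check the labels")
  res
}

#' Case-control differential expression by logistic regression
#'
#' Per transcript, fits `diagnosis ~ expression + sex + age` by logistic
#' (binomial) regression via iteratively reweighted least squares and
#' reports the Wald p-value of the expression coefficient (log-odds of AD
#' per transformed-expression unit). Transcripts with quasi-complete
#' separation or non-convergence are flagged and excluded from the
#' multiple-testing adjustment.
#'
#' @param expression an [expression_matrix()] object.
#' @param phenotypes phenotype data.frame with `diagnosis` ("AD"/"CN"),
#'   `sex`, `age`.
#' @param transform expression transform (see [transform_expression()]).
#' @param adjust `"BH"` (default) or `"none"`.
#' @return data.frame with `transcript_id`, `estimate`, `se`, `p`, `padj`,
#'   `flagged`.
#' @export
case_control_deg <- function(expression, phenotypes, transform = "log2p1",
                             adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  phenotypes <- validate_phenotypes(phenotypes)
  if (!"diagnosis" %in% names(phenotypes))
    stop("phenotypes need a 'diagnosis' column")
  samples <- intersect(rownames(expression$tpm), phenotypes$sample_id)
  ph <- phenotypes[match(samples, phenotypes$sample_id), ]
  if (length(unique(ph$diagnosis)) < 2)
    stop("both diagnosis classes (AD, CN) must be present")
  yy <- as.integer(ph$diagnosis == "AD")
  E <- transform_expression(expression$tpm[samples, , drop = FALSE], transform)
  res <- lapply(colnames(E), function(tx) {
    df <- data.frame(d = yy, expr = E[, tx], sex = ph$sex, age = ph$age)
    fit <- suppressWarnings(stats::glm(d ~ expr + sex + age, data = df,
                                       family = stats::binomial()))
    probs <- fit$fitted.values
    sep <- !fit$converged || any(probs > 1 - 1e-8) || any(probs < 1e-8) ||
      abs(stats::coef(fit)[["expr"]]) > 20
    cf <- summary(fit)$coefficients
    data.frame(transcript_id = tx,
               estimate = cf["expr", "Estimate"],
               se = cf["expr", "Std. Error"],
               p = cf["expr", "Pr(>|z|)"],
               flagged = sep, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (any(res$flagged))
    message("case_control_deg: ", sum(res$flagged),
            " transcript(s) flagged (separation/non-convergence), ",
            "excluded from adjustment")
  res$padj <- NA_real_
  ok <- !res$flagged
  res$padj[ok] <- if (adjust == "BH") stats::p.adjust(res$p[ok], "BH")
                  else res$p[ok]
  rownames(res) <- NULL
  res[, c("transcript_id", "estimate", "se", "p", "padj", "flagged")]
}

#' Differential expression between extreme quartile groups of a target
#'
#' Splits samples by a target transcript's expression into a high group
#' (strictly above the third quartile) and a low group (strictly below the
#' first quartile); samples inside `[Q1, Q3]` are never assigned. Empirical
#' quartiles use the linear-interpolation convention (`stats::quantile`
#' type 7). Per transcript, the groups are compared on transformed
#' expression (two-sample Welch t-test by default, Wilcoxon optional); fold
#' change is the ratio of group mean TPMs with pseudocount `eps`, reported
#' in whichever direction exceeds 1 with `direction` giving the higher
#' group. Significance is Bonferroni-adjusted p < `alpha` and fold change >
#' `fc_min`.
#'
#' @param target_expr TPM vector of the target transcript over samples
#'   (names = sample ids, aligned with `expression`).
#' @param expression an [expression_matrix()] object.
#' @param transform expression transform for the test.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @param eps pseudocount in TPM for the fold change (default 0.01).
#' @param alpha,fc_min significance thresholds (defaults 0.05 and 2).
#' @return data.frame with `transcript_id`, `mean_high`, `mean_low`,
#'   `fold_change`, `direction`, `p`, `padj` (Bonferroni), `significant`;
#'   attribute `groups` records the sample assignment.
#' @export
quartile_deg <- function(target_expr, expression, transform = "log2p1",
                         test = c("t", "wilcoxon"), eps = 0.01,
                         alpha = 0.05, fc_min = 2) {
  test <- match.arg(test)
  samples <- rownames(expression$tpm)
  if (length(target_expr) != length(samples))
    stop("target_expr must align with the expression samples")
  if (length(samples) < 8) stop("need at least 8 samples")
  qs <- stats::quantile(target_expr, c(0.25, 0.75), type = 7, names = FALSE)
  high <- which(target_expr > qs[2])
  low <- which(target_expr < qs[1])
  if (length(high) < 3 || length(low) < 3)
    stop("fewer than 3 samples in a quartile group (high = ", length(high),
         ", low = ", length(low), ")")
  E <- transform_expression(expression$tpm, transform)
  res <- lapply(colnames(E), function(tx) {
    eh <- E[high, tx]; el <- E[low, tx]
    p <- if (test == "t") {
      if (stats::var(eh) == 0 && stats::var(el) == 0) {
        if (mean(eh) == mean(el)) 1 else 0
      } else stats::t.test(eh, el)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(eh, el, exact = FALSE)$p.value)
    }
    mh <- mean(expression$tpm[high, tx]); ml <- mean(expression$tpm[low, tx])
    fc <- (mh + eps) / (ml + eps)
    data.frame(transcript_id = tx, mean_high = mh, mean_low = ml,
               fold_change = max(fc, 1 / fc),
               direction = if (fc >= 1) "high" else "low",
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- pmin(1, res$p * nrow(res))
  res$significant <- res$padj < alpha & res$fold_change > fc_min
  rownames(res) <- NULL
  attr(res, "groups") <- list(high = samples[high], low = samples[low],
                              q1 = qs[1], q3 = qs[2])
  res
}

#' Overlap between primary and replication scans
#'
#' A pair replicates when it is significant in the primary scan
#' (q < `fdr_primary`) and in the replication scan (q < `fdr_replication`).
#'
#' @param primary,replication scan tables from [run_scan()].
#' @param fdr_primary,fdr_replication thresholds (defaults 0.05 and 0.1).
#' @return list with counts and fractions of replicated pairs and
#'   transcripts, plus the replicated rows.
#' @export
replication_overlap <- function(primary, replication, fdr_primary = 0.05,
                                fdr_replication = 0.1) {
  key <- function(s) paste(s$transcript_id, s$variant_id, s$probe_id,
                           sep = "\r")
  kp <- key(primary); kr <- key(replication)
  shared <- intersect(kp, kr)
  if (!length(shared)) {
    warning("no shared triplets between the scans")
    return(list(n_primary_sig = 0L, n_replicated = 0L, frac_pairs = NaN,
                n_transcripts = 0L, frac_transcripts = NaN,
                replicated = primary[0, ]))
  }
  sig_p <- !is.na(primary$q) & primary$q < fdr_primary
  sig_r <- !is.na(replication$q) & replication$q < fdr_replication
  prim_sig_keys <- kp[sig_p]
  repl_keys <- intersect(prim_sig_keys, kr[sig_r])
  replicated <- primary[kp %in% repl_keys, , drop = FALSE]
  tx_prim <- unique(primary$transcript_id[sig_p])
  tx_repl <- unique(replicated$transcript_id)
  list(
    n_primary_sig = sum(sig_p),
    n_replicated = length(repl_keys),
    frac_pairs = if (sum(sig_p)) length(repl_keys) / sum(sig_p) else NaN,
    n_transcripts = length(tx_repl),
    frac_transcripts = if (length(tx_prim)) length(tx_repl) / length(tx_prim)
                       else NaN,
    replicated = replicated
  )
}

#' Concordance of -log10 p-values between two scans
#'
#' Pearson correlation of `-log10(p)` over the triplets shared by two scan
#' tables (degenerate rows dropped). Used to compare covariate models.
#'
#' @param scan_a,scan_b scan tables from [run_scan()].
#' @return Pearson correlation coefficient.
#' @export
neglogp_concordance <- function(scan_a, scan_b) {
  key <- function(s) paste(s$transcript_id, s$variant_id, s$probe_id,
                           sep = "\r")
  ka <- key(scan_a); kb <- key(scan_b)
  shared <- intersect(ka[!is.na(scan_a$p)], kb[!is.na(scan_b$p)])
  if (length(shared) < 3) stop("fewer than 3 shared non-degenerate triplets")
  pa <- scan_a$p[match(shared, ka)]
  pb <- scan_b$p[match(shared, kb)]
  tiny <- .Machine$double.xmin
  stats::cor(-log10(pmax(pa, tiny)), -log10(pmax(pb, tiny)))
}
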