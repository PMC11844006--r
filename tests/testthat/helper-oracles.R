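# Independent reference implementations used to cross-check the package.
# These deliberately use naive algorithms (enumeration, brute force) and do
# not share code with the implementation under test.

# step-up Benjamini-Hochberg, written out naively
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

# two-sided Fisher exact p by full enumeration of the hypergeometric support
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided exact Wilcoxon by enumeration over index splits of the pooled
# sample, recomputing midranks from the raw values for every split
enum_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  splits <- utils::combn(length(pooled), nx)
  u_all <- apply(splits, 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# optimal two-cluster split of 1-D data: try every sorted threshold, score
# within-cluster SS from scratch
brute_split <- function(x) {
  ord <- order(x)
  n <- length(x)
  best <- Inf; bestk <- 1
  for (k in 1:(n - 1)) {
    lo <- x[ord[1:k]]; hi <- x[ord[(k + 1):n]]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best) { best <- wss; bestk <- k }
  }
  labels <- rep("high", n)
  labels[ord[1:bestk]] <- "low"
  factor(labels, levels = c("low", "high"))
}

# greedy LD clumping, re-derived independently: per group, repeatedly pick
# the lowest-p remaining pair and drop everything its SNP tags
brute_clump <- function(tab, dosage, r2_threshold, group_key) {
  retained <- logical(nrow(tab))
  for (k in unique(group_key)) {
    left <- which(group_key == k)
    while (length(left)) {
      o <- left[order(tab$p[left])]
      idx <- o[1]
      retained[idx] <- TRUE
      left <- setdiff(left, idx)
      drop <- left[vapply(left, function(j) {
        r <- suppressWarnings(stats::cor(dosage[, tab$variant_id[idx]],
                                         dosage[, tab$variant_id[j]]))^2
        !is.na(r) && r >= r2_threshold
      }, logical(1))]
      left <- setdiff(left, drop)
    }
  }
  which(retained)
}

# minimal scan-shaped table for clumping tests
scan_stub <- function(transcript_id, variant_id, probe_id, p) {
  data.frame(transcript_id = transcript_id, variant_id = variant_id,
             probe_id = probe_id, p = p, q = p, significant = TRUE,
             stringsAsFactors = FALSE)
}
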