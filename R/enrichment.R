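#' Regulatory-peak overlap enrichment of significant features
#'
#' Classifies each feature as inside/outside the peak set and tests the
#' significant-vs-background split with a two-sided Fisher's exact test on
#' the disjoint 2x2 table (the background cells exclude the significant
#' features, so the rows partition the tested set). The odds ratio is the
#' sample odds ratio `(sig_in * bg_out) / (sig_out * bg_in)`; when any cell
#' is zero, 0.5 is added to all four cells for the OR only (Haldane), not
#' for the p-value.
#'
#' @param sig_features,background_features data.frames with `feature_id`,
#'   `chrom`, `pos` (1-based); significant features must be a subset of the
#'   background (the full tested set).
#' @param peaks a `gxm_peaks` object from [read_bed_peaks()].
#' @param marker label for the peak set (e.g. "H3K27me3").
#' @return data.frame (one row) with `marker`, `sig_in`, `sig_out`, `bg_in`,
#'   `bg_out`, `odds_ratio`, `p`.
#' @export
peak_overlap_enrichment <- function(sig_features, background_features, peaks,
                                    marker = "peaks") {
  if (!all(sig_features$feature_id %in% background_features$feature_id))
    stop("significant features must be a subset of the background set")
  if (nrow(sig_features) == nrow(background_features))
    stop("background must contain non-significant features")
  bg_only <- background_features[
    !background_features$feature_id %in% sig_features$feature_id, ,
    drop = FALSE]
  sig_hit <- positions_in_peaks(sig_features$chrom, sig_features$pos, peaks)
  bg_hit <- positions_in_peaks(bg_only$chrom, bg_only$pos, peaks)
  tab <- matrix(c(sum(sig_hit), sum(!sig_hit), sum(bg_hit), sum(!bg_hit)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("sig", "bg"), c("in", "out")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  ct <- tab
  if (any(ct == 0)) ct <- ct + 0.5
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  data.frame(marker = marker,
             sig_in = tab[1, 1], sig_out = tab[1, 2],
             bg_in = tab[2, 1], bg_out = tab[2, 2],
             odds_ratio = or, p = p, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of score distributions
#'
#' Compares a significant set's values (e.g. RegulomeDB scores or absolute
#' TSS distances) with the background's. Uses exact enumeration over all
#' rank splits when both groups have at most `exact_max` observations
#' (midrank ties handled by permutation of the observed values); otherwise
#' the normal approximation with midrank ties and continuity correction.
#'
#' @param sig_values,background_values numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`
#'   (direction refers to `sig_values`).
#' @param exact_max group-size bound for the exact path (default 8).
#' @return list with `statistic` (Mann-Whitney U of the significant group),
#'   `p`, and `method`.
#' @export
rank_shift_test <- function(sig_values, background_values,
                            alternative = c("two.sided", "less", "greater"),
                            exact_max = 8) {
  alternative <- match.arg(alternative)
  x <- sig_values; y <- background_values
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    warning("all values identical; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p = 1,
                method = "degenerate"))
  }
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    # exact permutation distribution of U over all rank splits
    splits <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[splits], nrow = nx)) - nx * (nx + 1) / 2
    p <- switch(alternative,
      less = mean(u_all <= u_obs),
      greater = mean(u_all >= u_obs),
      two.sided = min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    )
    return(list(statistic = u_obs, p = p, method = "exact"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = FALSE, correct = TRUE))
  list(statistic = u_obs, p = wt$p.value, method = "normal")
}

#' Monte-Carlo gene-family enrichment
#'
#' Draws `n_trials` gene sets of the significant set's size uniformly
#' without replacement from the universe and counts how often the family
#' membership reaches the observed count. The empirical p-value uses the
#' `(1 + hits) / (n_trials + 1)` correction, so its floor is
#' `1 / (n_trials + 1)`. The exact hypergeometric tail is reported
#' alongside as a cross-check.
#'
#' @param sig_genes,universe_genes,family_genes character vectors;
#'   `sig_genes` and `family_genes` must be subsets of `universe_genes`.
#' @param n_trials number of Monte-Carlo draws (default 1e6).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return list with `observed`, `expected`, `p_empirical`,
#'   `p_hypergeometric`, `n_trials`.
#' @export
family_enrichment <- function(sig_genes, universe_genes, family_genes,
                              n_trials = 1e6, seed = 1) {
  sig_genes <- unique(sig_genes)
  universe_genes <- unique(universe_genes)
  family_genes <- unique(family_genes)
  if (!all(family_genes %in% universe_genes))
    stop("family genes must be a subset of the universe")
  if (!all(sig_genes %in% universe_genes))
    stop("significant genes must be a subset of the universe")
  k <- length(sig_genes)
  N <- length(universe_genes)
  if (k > N) stop("significant set larger than universe")
  fam <- universe_genes %in% family_genes
  observed <- sum(sig_genes %in% family_genes)
  hits <- .with_seed(seed, {
    h <- 0L
    for (b in seq_len(ceiling(n_trials / 1e5))) {
      nb <- min(1e5, n_trials - (b - 1) * 1e5)
      h <- h + sum(vapply(seq_len(nb),
                          function(i) sum(fam[sample.int(N, k)]) >= observed,
                          logical(1)))
    }
    h
  })
  m <- sum(fam)
  list(observed = observed,
       expected = k * m / N,
       p_empirical = (1 + hits) / (n_trials + 1),
       p_hypergeometric = stats::phyper(observed - 1, m, N - m, k,
                                        lower.tail = FALSE),
       n_trials = n_trials)
}
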