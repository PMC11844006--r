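#' Transform a TPM matrix or vector for model fitting
#'
#' @param tpm non-negative TPM values.
#' @param method `"log2p1"` (default, `log2(TPM + 1)`), `"log2"`
#'   (`log2(TPM)`, requires TPM > 0), `"identity"`, or `"rankinv"`
#'   (rank-based inverse-normal, Blom offset 3/8, applied per transcript).
#' @return transformed values, same shape as the input.
#' @export
transform_expression <- function(tpm, method = c("log2p1", "log2", "identity",
                                                 "rankinv")) {
  method <- match.arg(method)
  switch(method,
    log2p1 = log2(tpm + 1),
    log2 = {
      if (any(tpm <= 0, na.rm = TRUE))
        stop("log2 transform requires strictly positive TPM")
      log2(tpm)
    },
    identity = tpm,
    rankinv = {
      rint <- function(x) {
        r <- rank(x, na.last = "keep")
        stats::qnorm((r - 3 / 8) / (sum(!is.na(x)) + 1 / 4))
      }
      if (is.matrix(tpm)) apply(tpm, 2, rint) else rint(tpm)
    }
  )
}

# Gaussian OLS fit with log-likelihood at the MLE residual variance.
# Returns a degenerate stub when the design is rank-deficient or the fit is
# numerically perfect (residual variance ~ 0, where the Gaussian likelihood
# diverges).
.ols_fit <- function(X, y) {
  n <- length(y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p)
    return(structure(list(degenerate = TRUE, reason = "rank-deficient design",
                          n_used = n, n_params = p), class = "gxm_fit"))
  coef <- qr.coef(qx, y)
  res <- y - X %*% coef
  rss <- sum(res^2)
  sigma2 <- rss / n
  if (sigma2 < 1e-12 * max(1, stats::var(y)))
    return(structure(list(degenerate = TRUE, reason = "zero residual variance",
                          n_used = n, n_params = p), class = "gxm_fit"))
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtx_inv) * rss / (n - p))
  names(se) <- colnames(X)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(list(coefficients = stats::setNames(as.vector(coef), colnames(X)),
                 se = se, sigma2 = sigma2, rss = rss, loglik = loglik,
                 n_used = n, n_params = p, df_residual = n - p,
                 degenerate = FALSE, reason = NA_character_),
            class = "gxm_fit")
}

#' @export
print.gxm_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<gxm_fit> degenerate:", x$reason, "\n")
  } else {
    cat("<gxm_fit> n =", x$n_used, ", params =", x$n_params,
        ", logLik =", signif(x$loglik, 6), "\n")
    print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  }
  invisible(x)
}

#' Fit the reduced and full interaction models for one triplet
#'
#' Ordinary least squares of transformed expression on the reduced design
#' `y ~ g + m + covariates` and the full design `y ~ g + m + g:m +
#' covariates`, with the interaction column the element-wise product of
#' dosage and methylation. Dosage is coded additively (0/1/2 minor alleles);
#' missing dosages are mean-imputed; samples with missing `y`, `m` or
#' covariates are dropped from both fits.
#'
#' @param y transformed expression per sample (see [transform_expression()]).
#' @param g minor-allele dosage per sample (NA allowed, mean-imputed).
#' @param m methylation beta per sample.
#' @param covars optional numeric matrix or data.frame of covariates
#'   (columns named), same sample order.
#' @return list with elements `reduced` and `full`, each a `gxm_fit` (either
#'   may be degenerate: rank-deficient design or zero residual variance).
#' @export
fit_triplet <- function(y, g, m, covars = NULL) {
  n <- length(y)
  stopifnot(length(g) == n, length(m) == n)
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    stopifnot(nrow(covars) == n)
  }
  g <- .impute_mean(g)
  keep <- !is.na(y) & !is.na(g) & !is.na(m)
  if (!is.null(covars)) keep <- keep & stats::complete.cases(covars)
  y <- y[keep]; g <- g[keep]; m <- m[keep]
  covars <- if (is.null(covars)) NULL else covars[keep, , drop = FALSE]
  p_full <- 4 + if (is.null(covars)) 0 else ncol(covars)
  if (length(y) < p_full + 2)
    stop("too few complete samples (", length(y), ") for ", p_full,
         " parameters")
  Xr <- cbind("(Intercept)" = 1, g = g, m = m)
  if (!is.null(covars)) Xr <- cbind(Xr, covars)
  Xf <- cbind(Xr[, 1:3, drop = FALSE], "g:m" = g * m)
  if (!is.null(covars)) Xf <- cbind(Xf, covars)
  list(reduced = .ols_fit(Xr, y), full = .ols_fit(Xf, y))
}

.impute_mean <- function(g) {
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  g
}

#' Likelihood-ratio test between nested Gaussian model fits
#'
#' `stat = 2 * (logLik_full - logLik_reduced)` clamped at zero, referred to
#' a chi-square distribution with `df` equal to the parameter difference
#' (1 for the single interaction term).
#'
#' @param reduced,full `gxm_fit` objects on the same samples.
#' @return list with `stat`, `df`, `p`.
#' @export
lrt <- function(reduced, full) {
  stopifnot(inherits(reduced, "gxm_fit"), inherits(full, "gxm_fit"))
  if (isTRUE(reduced$degenerate) || isTRUE(full$degenerate))
    stop("cannot test degenerate fits")
  if (reduced$n_used != full$n_used)
    stop("models fitted on different sample counts (", reduced$n_used,
         " vs ", full$n_used, ")")
  df <- full$n_params - reduced$n_params
  if (df < 1) stop("full model must have more parameters than reduced")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`; `NA`/`NaN` p-values
#' are excluded from the adjustment (their q is `NA`) with a reported count.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values, same length/order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  bad <- is.na(pvals)
  if (any(!bad & (pvals < 0 | pvals > 1)))
    stop("p-values outside [0, 1]")
  if (any(bad))
    message("bh_fdr: ", sum(bad), " missing p-value(s) excluded")
  q <- rep(NA_real_, length(pvals))
  q[!bad] <- stats::p.adjust(pvals[!bad], method = "BH")
  q
}

#' Run the G x M interaction scan over a triplet set
#'
#' For every triplet, fits the reduced model `T ~ G + M + covariates` and
#' full model `T ~ G + M + G*M + covariates` on transformed expression and
#' computes the 1-df likelihood-ratio test for the interaction term.
#' Degenerate triplets (rank-deficient design, e.g. constant methylation or
#' monomorphic dosage after subsetting, or a numerically perfect fit) are
#' flagged and excluded from the FDR adjustment, which is performed jointly
#' over all tested triplets.
#'
#' @param triplets data.frame with `transcript_id`, `variant_id`, `probe_id`
#'   (e.g. from [apply_qc()]).
#' @param genotypes,methylation,expression the three omics containers.
#' @param phenotypes phenotype data.frame (see [validate_phenotypes()]).
#' @param covariates character vector of phenotype columns to adjust for;
#'   `c("sex", "age")` is the primary model, `character(0)` and
#'   `c("sex", "age", "braak", "cerad", "apoe4")` the sensitivity models.
#' @param transform expression transform, see [transform_expression()].
#' @param fdr significance threshold on the BH q-value (default 0.05).
#' @param samples optional explicit sample subset; by default the
#'   intersection of all inputs' sample ids.
#' @return data.frame of class `gxm_scan` with one row per triplet:
#'   ids, `beta_gm`, `se_gm`, `lrt_stat`, `df`, `p`, `q`, `n_used`,
#'   `degenerate`, `reason`, `significant`. Attributes record the covariate
#'   set, transform and threshold.
#' @export
run_scan <- function(triplets, genotypes, methylation, expression, phenotypes,
                     covariates = c("sex", "age"), transform = "log2p1",
                     fdr = 0.05, samples = NULL) {
  phenotypes <- validate_phenotypes(phenotypes)
  if (is.null(samples))
    samples <- .common_samples(genotypes, methylation, expression, phenotypes)
  if (!nrow(triplets)) {
    warning("empty triplet set; returning empty scan table")
    return(.empty_scan(covariates, transform, fdr))
  }
  missing_cov <- setdiff(covariates, names(phenotypes))
  if (length(missing_cov))
    stop("covariates absent from phenotypes: ",
         paste(missing_cov, collapse = ", "))
  ph <- phenotypes[match(samples, phenotypes$sample_id), , drop = FALSE]
  covm <- if (length(covariates))
    as.matrix(as.data.frame(lapply(ph[covariates], as.numeric)))
  else NULL
  Y <- transform_expression(expression$tpm[samples, , drop = FALSE], transform)
  G <- genotypes$dosage[samples, , drop = FALSE]
  M <- methylation$beta[samples, , drop = FALSE]
  ty <- match(triplets$transcript_id, colnames(Y))
  gv <- match(triplets$variant_id, colnames(G))
  pm <- match(triplets$probe_id, colnames(M))
  if (anyNA(ty) || anyNA(gv) || anyNA(pm))
    stop("triplet ids missing from the matrices")

  nr <- nrow(triplets)
  beta_gm <- se_gm <- stat <- p <- rep(NA_real_, nr)
  n_used <- rep(NA_integer_, nr)
  degenerate <- logical(nr)
  reason <- rep(NA_character_, nr)
  for (i in seq_len(nr)) {
    fits <- tryCatch(fit_triplet(Y[, ty[i]], G[, gv[i]], M[, pm[i]], covm),
                     error = function(e) e)
    if (inherits(fits, "error")) {
      degenerate[i] <- TRUE
      reason[i] <- conditionMessage(fits)
      next
    }
    if (fits$reduced$degenerate || fits$full$degenerate) {
      degenerate[i] <- TRUE
      reason[i] <- if (fits$full$degenerate) fits$full$reason
                   else fits$reduced$reason
      next
    }
    lr <- lrt(fits$reduced, fits$full)
    beta_gm[i] <- fits$full$coefficients[["g:m"]]
    se_gm[i] <- fits$full$se[["g:m"]]
    stat[i] <- lr$stat
    p[i] <- lr$p
    n_used[i] <- fits$full$n_used
  }
  if (any(degenerate))
    message("run_scan: ", sum(degenerate),
            " degenerate triplet(s) excluded from FDR")
  q <- suppressMessages(bh_fdr(p))
  out <- data.frame(
    transcript_id = triplets$transcript_id,
    variant_id = triplets$variant_id,
    probe_id = triplets$probe_id,
    beta_gm = beta_gm, se_gm = se_gm,
    lrt_stat = stat, df = 1L, p = p, q = q,
    n_used = n_used, degenerate = degenerate, reason = reason,
    significant = !is.na(q) & q < fdr,
    stringsAsFactors = FALSE
  )
  attr(out, "covariates") <- covariates
  attr(out, "transform") <- transform
  attr(out, "fdr") <- fdr
  class(out) <- c("gxm_scan", "data.frame")
  out
}

.empty_scan <- function(covariates, transform, fdr) {
  out <- data.frame(transcript_id = character(), variant_id = character(),
                    probe_id = character(), beta_gm = numeric(),
                    se_gm = numeric(), lrt_stat = numeric(), df = integer(),
                    p = numeric(), q = numeric(), n_used = integer(),
                    degenerate = logical(), reason = character(),
                    significant = logical(), stringsAsFactors = FALSE)
  attr(out, "covariates") <- covariates
  attr(out, "transform") <- transform
  attr(out, "fdr") <- fdr
  class(out) <- c("gxm_scan", "data.frame")
  out
}
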