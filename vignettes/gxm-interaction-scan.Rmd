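---
title: "Scanning promoters for SNP-by-methylation interactions on transcript expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning promoters for SNP-by-methylation interactions on transcript expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxmscan)
```

## The question and the model

Genetic variants (SNPs) and DNA methylation each regulate transcription, but
their effects need not be additive: a promoter SNP's effect on expression can
depend on the methylation state of a nearby CpG. `gxmscan` tests for such
G x M interactions at transcript resolution. For every candidate triplet of a
transcript *T*, a promoter SNP *G* (minor-allele dosage 0/1/2) and a promoter
CpG probe *M* (beta value in [0, 1]), it compares two nested Gaussian linear
models on transformed expression:

* reduced: `T ~ G + M + sex + age`
* full: `T ~ G + M + G*M + sex + age`

by a likelihood-ratio test. The statistic `2 * (logLik_full - logLik_reduced)`
is referred to a chi-square distribution with one degree of freedom, because
dosage is coded additively and the interaction adds a single parameter.
Interaction pairs are called significant at a genome-wide Benjamini-Hochberg
FDR below 0.05, then reduced to LD-independent representatives by greedy
clumping at r^2 >= 0.8 (keep the lowest p per clump).

### Assumptions

* Expression is approximately log-linear in dosage, methylation and their
  product after the chosen transform, with i.i.d. Gaussian residuals.
* Dosage effects are additive (no dominance); the interaction has one degree
  of freedom. A factor coding of genotype would use two and is deliberately
  out of scope.
* Samples are exchangeable: no kinship, population structure or batch
  adjustment is performed (methylation matrices are expected to arrive
  already normalised).

## Promoter geometry

The promoter is the strand-aware window from 2,000 bp upstream to 200 bp
downstream of the transcription start site, closed at both ends and clipped
at chromosome position 1: `[TSS - 2000, TSS + 200]` on `+` transcripts,
`[TSS - 200, TSS + 2000]` on `-`. Signed TSS distances are positive
downstream in the direction of transcription. Candidate triplets are the full
cross product of in-window SNPs and probes per transcript, so a feature
shared by two overlapping promoters is tested in both. Window boundaries are
inclusive; an annotation source that intends half-open windows will differ by
at most one base.

## Quality control

Before fitting, a triplet is dropped when its SNP has cohort minor-allele
frequency at or below 0.05 (strict inequality required, so MAF exactly 0.05
is excluded), when the SNP is monomorphic in the analysis cohort, or when the
transcript's median TPM across all samples is at or below 0.1 (again strict).
Missing dosages are mean-imputed per variant at model-fit time only; the
stored matrices keep the missing calls so no information is destroyed at I/O
time.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `upstream`, `downstream` | 2000, 200 | bp | promoter definition above |
| `maf_min` | 0.05 | frequency | excludes rare SNPs with unstable fits |
| `tpm_median_min` | 0.1 | TPM | excludes essentially unexpressed transcripts |
| `fdr_primary` | 0.05 | q-value | discovery threshold |
| `fdr_replication` | 0.1 | q-value | looser threshold for replication cohorts |
| `r2_threshold` | 0.8 | r^2 | LD block boundary for clumping |
| `transform` | `log2p1` | - | `log2(TPM + 1)`; see below |
| `covariates` | `sex, age` | - | primary adjustment set |

## Numerical and design choices

**Expression transform.** The scan fits `log2(TPM + 1)` by default;
`log2`, `identity` and a rank-based inverse-normal transform are available.
The log scale is the field's default for TPM and matches the generative
scale of the synthetic cohorts; the pseudocount guards zero TPM. At the
synthetic baseline expression (log2 TPM around 8) the pseudocount perturbs
the scale by under 0.5%, so fitted interaction coefficients are essentially
on the generative scale.

**Chi-square versus F.** With one extra parameter and n in the hundreds, the
chi-square LRT and the nested-model F test order triplets identically (their
statistics are monotone transforms of each other); the chi-square version is
the default and the F statistic can be recovered from any fit. The
chi-square reference is mildly anticonservative in finite samples (about
0.052 at nominal 0.05 for n = 360), which the null-calibration check bounds.

**Degenerate fits.** A rank-deficient design (constant methylation, a SNP
monomorphic after subsetting) or a numerically perfect fit (residual
variance ~ 0, where the Gaussian likelihood diverges) flags the triplet as
degenerate; degenerate triplets are excluded from the FDR adjustment with a
recorded reason rather than contributing meaningless p-values.

**FDR pooling.** q-values are computed once across all tested triplets
genome-wide, not per transcript, matching a single genome-wide discovery
threshold.

**Clumping groups and ties.** Clumping competes SNPs within the same
(transcript, probe) pair by default — distinct probes may legitimately
retain correlated SNPs — and is configurable to transcript-wide or global
grouping. Ties in p are broken by chromosome, position and probe id so the
greedy procedure is deterministic. r^2 is computed from the analysis
cohort's dosages; a reference-panel VCF can be supplied instead by reading
it with `read_vcf_genotypes()` and passing it as the genotype argument.

**Fisher tables.** Peak-overlap enrichment builds a disjoint 2x2 table
(background cells exclude the significant features) so the rows partition
the tested set; the p-value is the exact two-sided Fisher test and the
reported odds ratio is the sample OR with a Haldane 0.5 correction only
when a cell is zero.

**Low/high methylation split.** The stratified-effect display splits
samples by two-group clustering of the probe's beta values. In one
dimension the two-cluster k-means optimum is a threshold in sorted order,
so the split is solved exactly by scanning all n - 1 thresholds and
minimising the within-cluster sum of squares. This is deterministic and
provably optimal, whereas restarted iterative k-means can converge to a
local optimum; the test suite verifies equality with an exhaustive search
on random inputs.

**Family enrichment.** The gene-family test draws `n_trials` random gene
sets of the observed size (default one million) and reports the
`(1 + hits) / (n_trials + 1)`-corrected empirical p, whose floor is
`1 / (n_trials + 1)`; the exact hypergeometric tail is reported alongside
as a cross-check, since for simple uniform sampling the two must agree.

**Quartile groups.** The quartile differential-expression comparison uses
strict inequalities around linear-interpolation (type 7) quartiles; samples
inside `[Q1, Q3]` are never assigned to either group. The group test is a
Welch t-test on transformed expression (Wilcoxon optional), the fold change
uses a 0.01 TPM pseudocount, and significance is Bonferroni p < 0.05 with
fold change > 2.

**Logistic DEG.** Case-control differential expression fits
`diagnosis ~ expression + sex + age` per transcript by IRLS; transcripts
showing quasi-complete separation or non-convergence are flagged and
excluded from the (configurable, BH by default) adjustment.

## The synthetic cohort generator

Real matched genotype/methylation/expression cohorts of this design are
controlled-access, so the package ships a generator that emulates the
statistical structure the scan assumes and records every planted effect:

* **Genotypes.** Each promoter carries an LD block: a Gaussian copula with
  AR(1) latent correlation `ld_rho` over two independent allele draws per
  sample gives Hardy-Weinberg marginals at the block's MAF and tunable
  dosage correlation between adjacent SNPs. MAF is drawn once per block —
  tightly linked variants share allele frequency, and a shared MAF is what
  makes near-perfect dosage correlation attainable. A latent correlation of
  0.999 yields dosage r^2 around 0.95.
* **Methylation.** Probe betas are Beta(0.5, 0.5) by default — the bimodal
  low/high mixture typical of array-wide CpG values, and the regime in
  which a low/high split is meaningful. An optional `meqtl_rho` couples
  probes to their promoter's lead SNP on the logit scale for robustness
  experiments; by default methylation is independent of genotype, since the
  scan must not require G-M correlation.
* **Expression.** `y = beta0 + beta_g G + beta_m M + beta_gm G*M +
  beta_sex sex + beta_age (age - 75) + e`, `e ~ N(0, noise_sd^2)`, with
  TPM = 2^y. Main effects act through each transcript's first SNP and
  probe; interactions act through a fixed-size random subset of triplets
  (`round(frac_interaction * n_triplets)`), all recorded in the truth
  table. The baseline `beta0 = 8` (TPM ~ 256) keeps the default scan
  transform a near-exact inverse of the generative scale.
* **Phenotypes.** Sex is Bernoulli(1/2); age is uniform on 65-90 years;
  CERAD is drawn so that about 73% of samples satisfy the CERAD <= 3 AD
  definition, and diagnosis follows it; Braak stage and APOE4 allele count
  are drawn independently as plausible covariate columns.

Everything is a deterministic function of the config including its seed
(byte-identical reruns). Derived seeds for pipeline stages come from the
single master seed.

What the generator does *not* emulate — and what passing checks therefore
do not establish about real data: probe chemistry and probe-type effects of
450K arrays, cell-type composition, batch structure, population
stratification and kinship, realistic LD beyond a within-promoter AR(1)
block, meQTL architecture (off by default), and any dependence of
diagnosis on expression.

## Study conditions used by the checks

The test suite and the acceptance script re-derive the package's
guarantees at these problem sizes, chosen to mirror a realistic cohort
(n = 360 samples, the scale of a single-region brain multi-omics study)
while staying desk-sized:

* **Null calibration**: 2,000 triplets, no planted effects; the LRT
  p-values pass a Kolmogorov-Smirnov test against U(0, 1) and reject at
  close to the nominal 5% rate.
* **FDR control**: 20 cohorts with 5% of 2,000 triplets carrying
  `beta_gm = 1` at MAF 0.3 and noise SD 1; the mean false-discovery
  proportion of the q < 0.05 set stays near or below the nominal level.
* **Effect recovery**: 500 single-triplet cohorts per sample size; the
  interaction estimate is unbiased to within 0.05 at n = 360 and its RMSE
  decreases over n = 90, 180, 360, 720.
* **End-to-end fixture**: 50 transcripts, two SNPs per promoter at dosage
  r^2 ~ 0.95, one probe, 10 planted interactions with `beta_gm = 1` and
  `noise_sd = 0.5`. The planted interaction's noncentrality is then large
  (roughly 75), so all planted triplets are recovered at q < 0.05 and
  clumping removes the LD twins; the run is reproducible bit-for-bit.
* **Covariate concordance**: with zero simulated sex/age effects, p-values
  from the adjusted and unadjusted models agree to Pearson r > 0.99 on
  -log10 scale.

## A worked example

```{r example, eval = FALSE}
library(gxmscan)

coh <- simulate_cohort(fixture_cohort_config())
res <- run_full_analysis(pipeline_config(seed = 101), cohort = coh)
res
res$clump$retained[, c("transcript_id", "variant_id", "probe_id", "q")]

# methylation-stratified view of the top pair
top <- res$clump$retained[1, ]
m <- coh$methylation$beta[, top$probe_id]
stratified_effect(log2(coh$expression$tpm[, top$transcript_id] + 1),
                  coh$genotypes$dosage[, top$variant_id],
                  split_by_methylation(m), m = m)
```

## Limitations

* The chi-square LRT is mildly anticonservative at moderate n; an exact-F
  variant of the same comparison differs only in the tail calibration, not
  the ranking.
* Clumping is greedy and marginal; it does not fine-map. Conditional or
  joint modelling of clumps is future work.
* The scan fits each triplet independently; shared SNPs or probes across
  triplets induce dependence that BH tolerates in practice but the package
  does not model.
* No adjustment for population structure, kinship or hidden confounders is
  provided; inputs are assumed pre-normalised.
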