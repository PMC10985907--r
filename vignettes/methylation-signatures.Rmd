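---
title: "Deriving and interrogating pan-cancer DNA methylation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and interrogating pan-cancer DNA methylation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsig)
```

## The model

`methsig` implements a pipeline for deriving conserved DNA methylation
signatures from Illumina-450K-style beta-value matrices and relating them to
genomic and clinical covariates. A beta value $\beta_{ij} \in [0,1]$ is the
methylated fraction of probe $j$ in sample $i$. The pipeline has five stages.

**1. Quality control.** Tumor samples are kept only when their estimated
purity is strictly above 0.6 (normals carry no purity and are always kept);
probes are dropped when they overlap a SNP, sit on chrX/chrY, or are missing
in strictly more than 10% of the retained samples; remaining gaps are filled
with the per-probe median across all samples. "Per-probe median" is the only
reading of median imputation that preserves probe-level methylation
structure, so that is what the package does. Missingness is assessed after
sample selection, because sample filters come first in the processing order.

**2. Conserved DMP calling.** For each probe we fit the linear model

$$\beta_{ij} = \beta_0 + \beta_1\,TY_i + \beta_2\,CY_{ik}
  + \beta_3\,(TY_i{:}CY_i) + TO_i + \varepsilon_{ij}$$

with tissue type $TY$ (tumor = 1), cancer type $CY$, their interaction, and
the tissue origin $TO$ as the patient blocking factor of the matched design
($TO$ absorbs the $CY$ main effects, which are constant within a patient).
The statistic fed to the permutation test is the joint F for all
tissue-effect columns ($TY$ and every $TY{:}CY$ column, $df_1 = $ number of
cancer types), reducing to $|t|$ of $TY$ with a single cancer type. We chose
the joint statistic so that a probe differential in *any* cancer type
registers. Significance comes from a within-pair permutation null: in each
of 1000 rounds every pair swaps its tumor/normal labels independently with
probability 1/2 (the same swap pattern for all probes, preserving
inter-probe correlation), and the empirical P is the add-one estimator
$(1 + \#\{\text{permuted} \ge \text{observed}\})/(1 + n_{\text{perm}})$, so
the smallest attainable P at 1000 rounds is $1/1001 < 0.001$, exactly
reaching the poised cutoff $P < 0.001$.

Each probe's effect size is the median over pairs of
$\Delta\beta = \beta_{\text{tumor}} - \beta_{\text{normal}}$. Poised probes
split by sign into hyper ($\bar{\Delta\beta} > 0$) and hypo; a probe with
median exactly 0 falls in the hypo branch and can never be conserved. The
conservation cutoffs are mirrored 5% percentiles: the hyper threshold is the
magnitude of the 5th percentile of the per-pair $\Delta\beta$ values pooled
over all poised hyper probes (the "5% extreme of low methylation"), the hypo
threshold mirrors it at the 95th percentile of the poised hypo pool.
Quantiles use the linear-interpolation definition, which is stated and
testable. The pooled per-pair reading is the default because a lower-tail
percentile of strictly positive medians could never be negative; the
median-distribution reading is available via `threshold_source = "median"`.

**3. Signature extraction by NMF.** The conserved-DMP beta matrix $V$
(probes × samples) is factorized as $V \approx E H$ with nonnegative weights
$E$ (probes × k, columns normalized to sum to one) and activities $H$
(k × samples). Factorization uses multiplicative updates with the
generalized Kullback–Leibler objective by default (the historical default of
the factorization packages in this field; Frobenius is available), best
objective over `n_runs = 30` random restarts, each restart seeded from a
named sub-stream of the master seed so results are reproducible. Signatures
of methylation loss can be extracted from $1-\beta$ via
`orientation = "one_minus_beta"`.

The rank is selected from consensus clustering: per candidate k, samples are
assigned to their maximal-activity signature in each of `n_runs` runs, and
the co-assignment frequencies form a consensus matrix. We report the
cophenetic correlation of the consensus dissimilarities against their
average-linkage dendrogram and the average silhouette width of the k-cut.
The selection rule picks the largest candidate passing the floors (0.95
cophenetic, 0.80 silhouette) before the first sustained cophenetic drop
(0.05 below the running maximum). When no drop exists the cophenetic profile
does not discriminate — with argmax assignment, surplus signatures rarely win
a sample, so consensus stays near-binary above the true rank — and the
silhouette peak decides, with exact ties breaking toward the smaller k. The
survey caps each run at 100 multiplicative-update iterations: cluster
assignments stabilize long before the objective converges, and the final
model is refit to full convergence at the chosen rank.

**4. Projection and cross-cohort comparison.** Fixed weights $E$ are
projected onto a new cohort by per-sample nonnegative least squares
$\hat h_i = \arg\min_{h \ge 0} \|E h - v_i\|_2$, after aligning on shared
probes (an error below 50% coverage). Signature sets are compared by cosine
similarity and Spearman correlation of weight columns with greedy
descending-cosine matching — optimal assignment buys nothing at $k \le 8$ and
greedy matching is trivially reproducible.

**5. Determinant genes and phenotype associations.** A gene's binary somatic
mutation status is the instrument, its expression the endogenous mediator,
and a signature activity the outcome. Genes pass a Wilcoxon rank-sum screen
(mutant vs wild-type activity, mutant count strictly above 10, BH FDR < 0.1)
and then two-stage least squares with cancer type as dummy covariates in
both stages (entering the covariate in only one stage is inconsistent).
Three gates are each BH-adjusted within their own family across the screened
genes of a signature: the Wu–Hausman endogeneity P (augmented-regression
form), the heteroscedasticity-robust first-stage F of the instrument (for a
single instrument this is the robust rank Wald F), and the 2SLS model Wald
P. A determinant gene needs all three FDRs below 0.05. Survival contrasts
median-split activity groups (ties go low; stratification by cancer type is
the caller's responsibility) through a Breslow-tie Cox model; per-cancer
Spearman correlations with immune features are combined into a meta-effect
by inverse-variance weighting on the Fisher-z scale with weights $n-3$;
variance attribution is the one-way between/total sum-of-squares ratio. The
immunotherapy-response model is a multivariate logistic regression of
response on activity (or its gene-expression surrogate), TP53 status and
FOXA1 expression — the response is binary and odds ratios are the natural
effect scale, though a linear-probability fit is available for parity with
the Gaussian-error formulation. The gene-expression surrogate (GES) ranks
genes by absolute Spearman correlation with activity on a training split,
keeps the top n (e.g. 156), scores samples as mean z-scored expression over
positively minus negatively correlated genes, and reports the held-out AUC
for separating high from low activity; z-scoring makes the score invariant
to per-gene affine rescaling.

## The synthetic-cohort generator

All tests run against `sim_config()` cohorts with full ground truth.

* **Paired cohorts.** Non-DMP probes share a baseline mean
  $\mu_j \sim U(0.05, 0.95)$ in both tissues; planted hyper/hypo probes
  shift the tumor mean by ±0.3 by default, clipped to (0.01, 0.99).
  Observed values are beta draws with mean $\mu$ and concentration 100
  (roughly ±0.05 noise at mid-range betas) — a beta-family noise model
  matches the [0,1] support and the heteroscedasticity of methylation
  fractions. A small additive per-cancer-type offset (sd 0.02) exercises
  the cancer-type covariate without committing to a biological model.
  Purity is drawn above 0.6 so QC passes; `contamination = TRUE` mixes
  tumor and normal means by $(1-\text{purity})$ to exercise the filter.
* **Signature cohorts.** `true_E` has near-disjoint supports (a random
  probe partition with 2% bleed-through), `true_H` is gamma-distributed
  with a 10-fold boost for each sample's cancer-type-linked signature, and
  $V = \mathrm{clip}(E H + \mathcal{N}(0, 0.02), 0, 1)$.
* **Causal chains.** For a determinant gene, mutations are Bernoulli(0.3),
  a shared confounder $u \sim \mathcal{N}(0, 1)$ enters both the expression
  equation (instrument strength $a_1 = 2$) and the overwritten activity
  (causal effect 2 by default), making expression endogenous while the
  instrument stays valid.
* **Outcomes.** Survival is exponential with rate
  $\lambda_0 e^{\theta z}$; censoring is independent exponential calibrated
  to the requested expected fraction. `hazard_on = "median_split"` applies
  the log hazard ratio to the above-median indicator instead, so the
  planted hazard ratio between median-split groups is exactly
  $e^\theta$ — the form used when a group-level hazard ratio is the target
  quantity. Age and immune features are tied to activity through a
  Gaussian copula; response follows the logistic model above.

One master seed drives a named sub-stream per operation
(`substream_seed()`), so regenerating any stage with the same seed is
byte-identical while stages stay decoupled.

What the generator does *not* emulate: probe-probe correlation beyond the
planted low-rank structure, cell-type composition, batch effects, detection
P values, or any calibration to real cohorts' distributions. Passing tests
therefore demonstrate the estimators' correctness and calibration under the
stated models, not performance on real arrays.

## Numerical choices and edge cases

* Empirical P uses the add-one estimator, so P = 0 never occurs.
* Residual-free probe fits (zero within-pair variance) return a sentinel
  statistic of $10^{12}$ (or its square root on the $|t|$ scale) instead of
  infinity, keeping permutation comparisons well defined.
* NMF updates floor denominators at $10^{-12}$; convergence is declared
  when the relative objective decrease over 10 iterations falls below the
  tolerance (default $10^{-6}$ for fits, $10^{-4}$ for rank surveys).
* Argmax assignments break ties toward the lowest signature index.
* Median splits send values equal to the median to the low group.
* A degenerate mirror rule (e.g. a nonnegative lower quantile of the hyper
  pool) warns and falls back to the magnitude of that quantile.
* Strata with fewer than 4 samples or constant values are excluded from
  per-cancer correlations with a warning; a single usable stratum returns
  its estimate as the meta-effect, flagged.

## Problem sizes used in the checks

The package's own verification runs at desk scale: permutation calibration
and DMP recovery use 2,000 probes × 40 pairs × 3 cancer types at 1,000
rounds; rank and weight recovery uses 1,500 probes × 300 samples with four
planted signatures at noise sd 0.02 and 30 restarts; instrumental-variable
calibration uses 100 replicates of n = 1000 with 200-replicate size/power
checks for the endogeneity test; survival recovery uses n = 500 with 20%
censoring. These sizes make every property check reproducible on a single
CPU while leaving the estimators' asymptotics clearly visible.

## Known limitations

* The orientation comparison (β vs 1−β) recovers matched activities with
  |Spearman| around 0.8 on the synthetic signature cohorts, not higher: with
  $V = EH$, the complement $1-V$ equals a rank-one background minus $EH$,
  so its best rank-k nonnegative factorization genuinely mixes background
  into every component. On real hypomethylation matrices — where beta values
  sit on a high, roughly constant baseline and signatures carve losses out
  of it — the two orientations share their dominant structure far more
  directly. The generator keeps the simple low-rank form deliberately; the
  comparison's output reports what it finds.
* Rank selection assumes the candidate range brackets the truth and that
  signatures separate samples; overlapping activity profiles without a
  dominant signature per sample weaken the consensus signal.
* The weak-instrument F collapses to the single-instrument robust Wald F;
  multi-instrument designs are out of scope.
* Cox fits use a single binary covariate; multivariable survival modeling
  beyond optional stratification is out of scope.

## A worked example

```{r example, eval = FALSE}
library(methsig)

cfg <- sim_config(n_pairs = 40, n_probes = 2000, seed = 1)
cohort <- simulate_paired_cohort(cfg)
clean <- qc_pipeline(cohort$beta)

dmps <- dmp_call(clean, n_perm = 1000, seed = 7)
summary(dmps)

conserved <- dmps$table$probe_id[dmps$table$conserved]
sig_cfg <- sim_config(n_probes = 1500, k_true = 4, n_cancer_types = 4,
                      seed = 7)
tumors <- simulate_signature_cohort(sig_cfg, n_samples = 300)
survey <- rank_survey(tumors$beta$values, k_range = 2:6, n_runs = 30,
                      seed = 3)
fit <- meth_nmf(tumors$beta$values, attr(survey, "chosen_k"), n_runs = 30,
                seed = 3)
print(fit)
activities <- predict(fit, tumors$beta$values)
```
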