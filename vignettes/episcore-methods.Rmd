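---
title: "Methylation-based protein scores: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based protein scores: models, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcore)
```

## The problem

Plasma protein levels carry prognostic information for many age-related
diseases, but proteomic assays are expensive and protein measurements are
noisy snapshots. Blood DNA methylation, measured routinely on arrays in
large cohorts, captures slower-moving regulatory state. An *EpiScore* is a
sparse linear predictor of a circulating protein's level built from CpG
methylation: a weighted sum of standardized beta values at a few dozen to a
few hundred CpG sites. Once trained, the weight file is portable — any
cohort with array methylation can compute the score and relate it to
outcomes, years before disease onset.

This package implements the full workflow: preprocessing of protein and
methylation matrices, penalised training, out-of-sample validation and
selection, projection into new cohorts, and incident-disease association
with nested Cox proportional-hazards models. A synthetic-cohort generator
with planted ground truth makes every stage testable, because the real
training cohorts for such scores are typically under restricted access.

## Preprocessing model

**Protein levels** are first mapped through a rank-based inverse normal
transformation (INT),
\[ z_i = \Phi^{-1}\!\left(\frac{r_i - c}{n - 2c + 1}\right), \]
with tie-averaged ranks \(r_i\) and offset \(c = 3/8\) (Blom). The offset
choice is not critical — any common constant gives almost identical
quantiles — but Blom is the default in genetics pipelines, and the offset is
configurable (`rank_inverse_normal(x, offset=)`). INT makes the training
outcome robust to heavy-tailed assay distributions and puts every protein on
the same scale.

**Residualization.** Protein levels are then regressed on age, sex, any
supplied covariates (genetic PCs, batch), and — per protein — the dosage
columns of its known pQTLs, so that the trained scores capture epigenetic
rather than common genetic or demographic signal. Residuals are exact
least-squares residuals: orthogonal to every design column and mean zero.
Whether published pQTL adjustments used additive dosages or hard calls is
often unstated; this package takes additive dosages in `[0, 2]`, the most
common convention.

**Methylation** is standardized per probe to mean 0, variance 1, with the
sample (\(n-1\)) variance denominator — stated explicitly because it changes
the scale of projected scores. When a cohort was processed in batches
("sets"), scaling is done separately per (probe, set) stratum. Two
degenerate-input rules keep projection robust rather than strict:

* probes constant within a stratum map to all-zero and are reported in a
  flagged-probe table, so projecting an externally trained weight set never
  aborts;
* missing beta values are mean-imputed within (probe, set), equivalent to a
  zero contribution after standardization, with per-probe missingness
  logged.

## Elastic-net training

For protein \(y\) (residualized) and standardized CpG matrix \(X\), the
trainer minimises
\[
\frac{1}{2n}\lVert y - b_0 - Xb\rVert^2
  + \lambda\left(\alpha\lVert b\rVert_1
  + \frac{1-\alpha}{2}\lVert b\rVert_2^2\right),
\qquad \alpha = 0.5,
\]
by cyclic coordinate descent with soft-thresholding, warm starts along a
100-point log-linear penalty path from
\(\lambda_{\max} = \max_j |x_j^\top y|/(n\alpha)\) (the smallest penalty
with an all-zero solution) down to \(\lambda_{\max}\cdot 10^{-3}\)
(\(10^{-2}\) when \(p \ge n\)), and sequential strong-rule screening for
speed. Solutions returned at a single penalty are polished until the
subgradient stationarity conditions hold to better than \(10^{-6}\); the
test suite checks this (and agreement with brute-force grid minimisation on
small problems, and with glmnet) on every run.

The penalty is chosen by K-fold cross-validation (10 folds by default; fold
assignment is a seeded uniform permutation, sizes differing by at most one).
The default selection rule is the CV-error-minimising \(\lambda\), which
targets out-of-sample correlation — the quantity the selection stage
thresholds. The more conservative one-standard-error rule is available
(`enet_config(rule = "1se")`); under pure-noise outcomes it returns the
empty model in the majority of runs, while the minimising rule admits a few
noise CpGs, which the downstream test-set selection filter then rejects.
An intercept is fitted but not stored in weight files: inputs are
standardized and projected scores are later rank-normalised, so a constant
shift is irrelevant.

A protein whose chosen model has zero nonzero weights is returned as an
explicitly empty weight set flagged "no features selected" — with
epigenome-scale feature sets a substantial fraction of proteins genuinely
yield no methylation signal, and the pipeline treats that as a result, not
an error.

## Validation, selection, projection

Trained scores are projected into an independent test cohort
(`project_episcores()`), and each score is correlated with the measured,
residualized protein (`evaluate_episcores()`): Pearson \(r\), a two-sided
p-value from the t-distribution on \(n-2\) df, and a 95% CI via the Fisher
z-transform (the CI method is a package choice; the interval is what
standard forest plots of validation performance show). Selection applies the
strict rule \(r > 0.1\) and \(p < 0.05\) in **at least one** configured test
set; scores with no external test data may fall back to a holdout
validation. Both thresholds are arguments; equality fails by design. The
provenance of the passing test set is recorded.

Projection onto any beta matrix standardizes per (probe, set) and takes the
weighted sum over the weight CpGs present. CpGs absent from the target array
contribute zero — mean imputation on the standardized scale — and per-score
probe coverage is reported so users can filter scores computed from too few
probes. This convention lets weight sets trained on one array generation
project onto another without failure.

## Incident-disease association

Projected scores are rank-inverse-normalised (hazard ratios are therefore
per 1 SD of score) and entered into Cox proportional-hazards models, one
(score, disease) cell at a time:

1. **Basic model**: score + age + sex (+ methylation set where present).
2. **FDR control**: Benjamini–Hochberg across the *entire* grid — the
   family is fixed at `n_scores x n_diseases` regardless of which cells
   converged.
3. **Fully adjusted model**: cells passing FDR (q < 0.05) are refit with
   lifestyle covariates (smoking score, deprivation, BMI, education,
   alcohol); a cell *passes the nested filter* iff basic q < 0.05 **and**
   full-model p < 0.05.
4. **Sensitivity layers**: further covariate blocks (estimated white-cell
   proportions, an epigenetic-aging score) are added cumulatively and the
   surviving cells refit. These are consumed as plain covariate columns;
   computing them is out of scope.

The Cox engine is the package's own Newton–Raphson maximiser of the partial
likelihood with Efron's tie correction (Breslow by flag; the two coincide
without ties, which the tests verify). Wald statistics are reported per
term. Nonconvergent or under-powered cells (below a configurable minimum
case count, default 10) are recorded with a status string and never abort
the grid. Family-structured cohorts can be handled approximately with a
shared gamma frailty per family (`frailty_by=`), fitted through
`survival::coxph`'s penalised frailty machinery; a full kinship-matrix
mixed Cox model is out of scope, and the frailty option is documented as an
approximation to it.

**Proportional-hazards diagnostics.** `schoenfeld_ph_test()` implements the
Grambsch–Therneau correlation-with-time score test on Schoenfeld residuals,
per term and global, with the identity time transform (the transform
matters little at these censoring patterns; identity is the choice here and
matches what `survival::cox.zph(transform = "identity")` computes — the two
agree numerically in the tests). Associations violating PH can be probed
with `followup_truncation()`, which recodes events beyond a yearly horizon
as censored and refits, tracing HR(h) across follow-up; under true
proportional hazards the trace is flat, while an early-confined effect
shrinks as the horizon grows.

**Binary outcomes.** `logistic_assoc()` fits per-score logistic models
(score + age at testing + sex) with Bonferroni correction at
`0.05 / n_scores`, flagging complete separation per score instead of
failing.

## The synthetic-cohort generator

`generate_cohort()` builds matched train/test/target cohorts sharing all
generative parameters but with disjoint, independently drawn samples:

* **Methylation**: latent Gaussians with equicorrelated blocks (default 20
  CpGs per block, within-block correlation 0.5), squashed through the
  inverse logit around per-probe means to beta values in (0, 1). Squashing
  latents — rather than drawing Beta variates — keeps the planted protein
  effects exactly linear on the latent scale while the observables remain
  array-like.
* **Proteins**: a variance-budgeted sum of an age effect (5% of variance),
  a sex effect (2%), pQTL dosage effects (10% over 2 variants per protein,
  MAF 0.1–0.5), a causal-CpG component whose share is the protein's
  methylation \(R^2\) (drawn per protein from 1%–58% by default, the span
  reported for real proteomes), and Gaussian noise. Budgets exceeding 1
  error out. Weights are scaled against the *theoretical* latent covariance
  so the planted \(R^2\) is exact in expectation.
* **Survival**: exponential event times with rate
  \(\lambda_0 \exp(\beta \cdot \text{score})\) per disease, where the score
  is the standardized true (noise-free) methylation component of the
  disease's driver protein, \(\lambda_0 = 0.02\)/year by default,
  administrative censoring at 14 years of follow-up plus 20% uniform early
  drop-out. A Weibull baseline can be emulated by transforming the times;
  the exponential is the default for closed-form sampling.

What the generator does *not* emulate: array chemistry and probe-level
measurement error, realistic LD between pQTL variants, cell-composition
confounding, or batch effects beyond the set-wise scaling structure. A
pipeline that passes the recovery tests is therefore shown to be correct
*given* linear signal and block-correlated features, not validated against
every failure mode of real arrays.

## Numerical choices and degenerate inputs

* Variance uses the \(n-1\) denominator everywhere.
* `compute_lambda_path()` refuses \(\alpha = 0\) (no finite
  \(\lambda_{\max}\); supply an explicit grid) and responses orthogonal to
  all predictors.
* Coefficients whose soft-threshold update is zero to rounding (relative
  magnitude below \(10^{-13}\)) are snapped to exact zero, so "all
  coefficients zero at \(\lambda \ge \lambda_{\max}\)" holds exactly.
* Cox fitting detects monotone likelihoods (perfect separation in risk
  sets) and errors rather than returning a divergent estimate; constant
  design columns are rejected up front.
* Ties in INT are rank-averaged; an all-tied vector maps to all zeros.
* The weight-file round trip is bit-exact (`%.17g` serialisation).

## Problem sizes used by the test and acceptance harnesses

The statistical checks run at sizes chosen to give stable Monte-Carlo
verdicts on one CPU in minutes: Wald-test calibration uses 2000 null
replicates at n = 500; Schoenfeld calibration 1000 replicates at n = 300
and power 200 replicates at n = 1000 against a coefficient crossing zero
mid-follow-up; BH control 500 replicates of m = 1000; end-to-end recovery
three synthetic cohorts of 500 training / 300 test samples, 2000 CpGs and
20 proteins (ten with planted \(R^2 = 0.25\), ten null); and hazard-ratio
CI coverage 200 replicates of n = 1000 with a planted log HR of 0.3 per SD.
The association-grid bookkeeping check uses the full 109-score by
12-disease layout, whose basic stage enters exactly 1308 tests into the FDR
family.

## Known limitations

* The gamma-frailty option approximates, but is not, a kinship-matrix
  random effect; with dense relatedness structures the fixed-effect SEs are
  the primary output to trust.
* Left truncation / age-as-timescale is not implemented; the models use
  time-on-study with age as a covariate.
* Probe liftover between array manifests is out of scope — projection
  relies on shared probe identifiers plus the missing-probe convention.
* The elastic-net trainer assumes the methylation matrix fits in memory;
  epigenome-wide (450k-probe) training is feasible but benefits from
  pre-filtering, which this package deliberately does not apply by default.
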