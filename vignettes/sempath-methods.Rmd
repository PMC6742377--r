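---
title: "Methods: SEM-based mapping of SNPs, intermediate phenotypes, and diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SEM-based mapping of SNPs, intermediate phenotypes, and diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sempath)
```

## The problem and the model

Hypertension and type 2 diabetes (T2D) share much of their etiology through
obesity. A single-SNP genome-wide scan answers only "which variants associate
with which outcome"; it says nothing about *how* genetic effects propagate
through correlated adiposity traits into disease. `sempath` implements a
four-step procedure that builds that quantitative map:

1. **Scan.** Each SNP is tested against each intermediate phenotype
   (linear regression) and each disease (logistic regression), adjusting
   for sex, area, and age. SNPs with p below a screening threshold
   (default 1e-5) form one *SNP block* per outcome.
2. **Latent genetic factors.** Each block is summarised by exploratory
   factor analysis: principal-component extraction on the dosage
   correlation matrix, factor count by the Kaiser rule (eigenvalues > 1),
   varimax rotation, and iterative exclusion of SNPs with communality
   below 0.3. Standardized factor scores (`FACTORij`, the j-th factor of
   block i) carry the blocks' joint genetic signal forward.
3. **Phenotype network.** Covariate-adjusted partial correlations among
   the three adiposity traits — subscapular skin fold (SUB, subcutaneous
   adiposity), BMI (overall adiposity), waist circumference (WC, abdominal
   adiposity) — and the two diseases, followed by a recursive path
   analysis under the clinically motivated ordering
   SUB → BMI → WC → T2D → HTN (ten directed edges; T2D is a risk factor
   for hypertension; central adiposity is the proximal driver of both
   diseases).
4. **Structural model.** The full model — factor scores regressed into
   their traits, traits cascading into diseases — is estimated by
   maximum-likelihood covariance-structure fitting, and every effect is
   decomposed into standardized direct, indirect, and total components.

The estimator is the classical Wishart ML discrepancy. With RAM matrices
`A` (directed paths), `S` (exogenous/residual covariances), and the
observed-variable filter `F`, the implied covariance is
`Sigma(theta) = F (I - A)^-1 S (I - A)^-T F^T` and

```
F_ML(theta) = ln|Sigma| + tr(S_obs Sigma^-1) - ln|S_obs| - p ,
```

minimised by BFGS with an analytic gradient; `(n - 1) F_ML` at the optimum
is the model chi-square. Standard errors come from the inverse information
(`2/(n-1) H^-1` with `H` the discrepancy Hessian). The standardized
solution rescales each path by the implied standard deviations of its
endpoints; the effect decomposition uses `total = (I - B)^-1 - I` on the
standardized path matrix `B`, with delta-method standard errors and the
star convention * p<.10, ** p<.05, *** p<.01.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 1e-5 | scan screening threshold (per outcome, no multiplicity correction — the published rule) |
| `communality_threshold` | 0.3 | minimum share of a SNP's variance explained by the common factors |
| `k_override` | Kaiser rule | per-block factor count override |
| `ld_prune_r2` | off | optional greedy LD pruning (keep the most significant SNP per LD cluster) |
| `gradient_tol` | 1e-8 | ML gradient-norm convergence tolerance |
| `B` (bootstrap) | 500 | case-resampling replicates for indirect-effect percentile intervals |

Two input modes exist throughout: raw data (all four steps) and *matrix
mode* (a labelled correlation matrix plus n), which skips steps 1–2 and
makes a published correlation table directly analysable —
`kare_phenotype_correlations()` ships the published covariate-adjusted
matrix (n = 8792; the slight deficit from the cohort's 8,842 subjects
reflects complete-case analysis and is preserved as printed).

## The synthetic cohort generator

Real cohort genotypes are under restricted access, so
`simulate_cohort(sim_config())` generates cohorts with the statistical
structure the analysis assumes:

* **Genotypes.** Per-SNP Hardy–Weinberg margins at a drawn minor-allele
  frequency; within-group correlation via a Gaussian copula (an
  equicorrelated latent normal thresholded at the HWE quantiles). The
  defaults use five groups sized 4/6/6/1/4, the block sizes retained after
  communality filtering in the motivating study.
* **Traits.** Latent factors are standardized equal-weight sums of their
  group's standardized dosages. Each trait's systematic part (cascade
  parents plus factor effects) is completed with an independent normal
  residual so the standardized core has unit population variance
  (residual variance `1 - w' C w` from the implied-covariance recursion;
  an inadmissible configuration is rejected with a diagnostic). Covariate
  effects (sex, area, age) are added on centred covariates afterward —
  small nonzero defaults, chosen only so covariate adjustment is
  exercised; the study does not report them.
* **Diseases.** A liability — linear in the trait cores, the disease's own
  factor effects, and covariates, with the standardized T2D indicator
  feeding the hypertension liability — is dichotomized at the empirical
  quantile matching the configured prevalence (defaults 9.45% T2D,
  27.06% hypertension). Clinical component measurements (blood pressure,
  glucose) are deliberately not simulated; the threshold is set by
  prevalence, not by mmHg/mg/dL.
* **Covariates.** Sex and area are Bernoulli with the cohort's observed
  proportions; age is uniform on 39–70 years (the study reports only
  mean, SD, and range; a uniform on the range is the simplest admissible
  choice).

Cascade coefficients default to the published standardized direct effects,
so the generator's default regime *is* the study's reported effect
structure. What the generator does **not** emulate: linkage-disequilibrium
maps of real chromosomes, population stratification, missingness,
medication effects, and assay noise. Passing tests therefore demonstrate
the statistical machinery is correct under the stated model, not that the
model captures every feature of real cohort data.

## Numerical choices

* **Extraction** is principal-component (loadings `sqrt(lambda_j) v_j`),
  matching the near-unity loadings legacy statistical packages produce;
  eigenvector signs are fixed so each column's largest-magnitude entry is
  positive, making results deterministic.
* **Varimax** is the Kaiser-normalized pairwise-rotation algorithm with
  the closed-form optimal angle per pair (`atan2` form), iterated to a
  criterion change below 1e-9. The closed-form angle matters: on perfectly
  balanced loadings the criterion has a saddle at the identity rotation
  where gradient-style updates stall.
* **Communality filtering** drops the lowest offender and re-extracts,
  iterating until all retained communalities reach the threshold; this
  removes order dependence relative to a single pass. A block can shrink
  to one SNP, which then loads 1.0 by construction.
* **ML fitting** starts from per-equation least squares wherever a path's
  endpoints are observed, with up to five deterministically jittered
  restarts. Outside the positive-definite region the objective returns a
  smooth eigenvalue penalty so the line search can recover. Numerically
  singular input covariances are rejected up front; the pipeline
  additionally drops factor scores that are near-linear combinations
  (R² ≥ 0.99) of earlier blocks' scores, the situation that arises when
  per-trait blocks share most of their SNPs.
* **Ties** in factor assignment go to the lower-indexed factor (logged).
* **Baseline model** for NFI/CFI is the independence model, whose ML
  solution is closed-form (`chi-square = -(n-1) ln|R|`).

## Design decisions made where the design was open

* Additive (0/1/2) genotype coding and Wald tests — the GWAS defaults.
* Covariate handling in the SEM: variables are residualized on covariates
  before covariance computation, so raw-data and matrix-mode fits are
  consistent by construction.
* Binary disease indicators enter correlations and ML fitting as numeric
  0/1. This replicates the estimator the motivating analysis used and is a
  documented limitation: liability-scale coefficients are attenuated by
  dichotomization, so the parameter-recovery guarantees in the test suite
  cover the continuous-trait cascade and the genetic factor effects, not
  the disease paths on the liability scale. No polychoric/DWLS machinery
  is provided.
* The chi-square uses the `(n - 1)` (Wishart) multiplier.
* The mediation ordering is an *input* (clinical reasoning), not the
  output of a causal-search algorithm; `default_disease_paths()` encodes
  the published ordering.
* Residual-covariance pairs (correlated measurement errors, e.g. for SNPs
  appearing in two blocks) are user-specified configuration; no automated
  modification-index search is performed.
* Indirect-effect inference: delta-method standard errors by default,
  nonparametric case-resampling percentile intervals as an option
  (`bootstrap_indirect()`); product-distribution methods are out of scope.

## Problem sizes used in the test suite

The suite exercises the generator and engine at sizes chosen to make the
statistical properties sharp but cheap: null-scan calibration uses 100
replicate scans of 200 SNPs at n = 500; chi-square calibration uses 500
replicates of a 1-df model at n = 500; parameter recovery uses 100 seeds
at n = 20,000 with two SNP groups; bootstrap coverage uses 20 seeds of
B = 200 at n = 500–2,000. The headline reproduction (matrix-mode fit of
the published 5×5 correlation matrix) is exact-deterministic and runs in
well under a second.

## Known limitations

* Normal-theory ML on 0/1 outcomes (see above).
* Factor scores stand in for latent variables in the structural model;
  the full latent measurement model with per-SNP indicators is expressible
  via `sem_spec(latent = ...)` but the pipeline's default is the
  score-based formulation.
* No genomic control, mixed-model association, kinship, or imputation in
  the scan; no oblique rotations or ML factor analysis in step 2.
* Matrix mode treats a correlation matrix as the covariance input; the
  standardized solution is invariant to this, but unstandardized
  quantities are only meaningful for genuine covariance input.
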