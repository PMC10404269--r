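---
title: "Multi-PGS stacking: models, simulation design and numerical choices"
author: "multipgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-PGS stacking: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A polygenic score (PGS) predicts a trait as a weighted sum of allele
dosages, with weights derived from genome-wide association study (GWAS)
summary statistics. Its accuracy is limited by the training GWAS sample
size; for many disorders that GWAS is small. Because traits are genetically
correlated, scores built for *other* traits carry information about the
target, and public repositories hold summary statistics for thousands of
traits. `multipgs` implements the three-step framework that exploits this:

1. **Build a PGS library.** Every available summary-statistics file is
   parsed through a column-name alias library, harmonized to an LD reference
   panel, filtered by a standard-deviation QC and a minimum-SNP gate, and
   turned into posterior-mean variant effects with a hyperparameter-free
   spike-and-slab Gibbs sampler (the LDpred-auto family). No per-score
   validation data are needed, so the library can be built "agnostically" —
   hundreds of scores, relevant or not.
2. **Train multi-PGS models.** The library is projected onto an
   individual-level cohort, standardized, and stacked together with
   covariates into a single predictor: L1-penalized regression with
   unpenalized covariates (the interpretable default), gradient-boosted
   trees, or a mixed form (boosted covariates, linear scores).
3. **Evaluate.** Five-fold cross-validation, covariate-adjusted variance
   explained on the observed and liability scales, AUC, quintile odds
   ratios, and percentile bootstrap confidence intervals; benchmarks against
   the single own-trait PGS, a genetic-parameter selection index (the
   wMT-SBLUP construction) and an individual-level BLUP (ridge) PGS.

Everything runs end-to-end on simulated data, so the pipeline is fully
testable without access-restricted cohorts.

## The spike-and-slab Gibbs sampler

All sampler math lives on the standardized-genotype, standardized-phenotype
scale, where a marginal GWAS estimate for variant $j$ satisfies
$\hat\beta_j \sim N\!\big((R\beta)_j,\, 1/n\big)$ with $R$ the block LD
matrix. Inputs on the allele-count scale are converted through the
scale-invariant z-statistic, $\hat\beta^{std}_j = z_j/\sqrt{n_j}$. The prior
is a point mass at zero with probability $1-p$ and a Gaussian slab
$N(0, h^2/(Mp))$ otherwise. One Gibbs sweep visits every variant, computes
the residual marginal effect through the block LD
($\tilde\beta_j = \hat\beta_j - (R\beta)_j + \beta_j$), and draws from the
two-component conditional posterior: slab mean
$\tilde\beta_j/(1 + Mp/(nh^2))$, slab variance $(1/n)/(1 + Mp/(nh^2))$,
inclusion probability from the Gaussian likelihood ratio. After each sweep
$p$ is resampled from $\mathrm{Beta}(1 + \#\text{causal},\, 1 + M -
\#\text{causal})$ and $h^2$ is recomputed as the quadratic form
$\beta^\top R \beta$ over blocks — the genetic variance under LD, not
$\sum_j \beta_j^2$.

Design choices that matter:

* **Rao–Blackwellised posterior means.** The reported per-chain effect
  vector is the average over post-burn-in sweeps of the *conditional* mean
  $q_j \cdot \mu_j$ rather than of the sampled $\beta_j$. Both estimate the
  posterior mean; the conditional-mean average has strictly smaller Monte
  Carlo variance, and in the identity-LD infinitesimal case ($p = 1$) it is
  exact in a single sweep. The chain state itself always uses sampled
  values, so the stationary distribution is untouched.
* **Chain grid and filtering.** Chains start from a log-spaced grid of $p$
  in $[10^{-4}, 0.9]$ with $h^2$ initialized at the LD-score-regression
  estimate (the full-scale run configuration is 30 chains, 800 burn-in, 400
  sampling iterations; the package's desk-scale default is 10/200/100,
  sized so a 20-file library builds in about a minute on one CPU). A chain
  is marked dead when its $h^2$ trace exceeds
  $\max(3 \cdot h^2_{init},\, 1)$ — on this scale a legitimate $h^2$ cannot
  exceed 1, so the floor only catches genuine explosions and a low
  initialization cannot kill healthy chains. Surviving chains are filtered
  by predictive scale: keep chains whose effect-vector standard deviation is
  at least $0.95\times$ the 95th percentile of chain scales, then average.
  If the band empties, the chain with the median $h^2$ is used and flagged.
  Both knobs are configuration-exposed because published tutorial practice
  has varied.
* **Test hooks.** `fix_p` / `fix_h2` freeze the hyperparameters, which makes
  the posterior exactly enumerable for small $M$ (the test suite checks a
  three-variant block against brute-force enumeration over all $2^3$ causal
  configurations) and reduces $p=1$ to the closed-form infinitesimal
  shrinkage $\hat\beta_j / (1 + M/(nh^2))$.

## LD-score regression

$h^2$ initialization regresses $\chi^2_j = (\hat\beta_j/se_j)^2$ on the LD
scores $\ell_j = \sum_k r_{jk}^2$ with a free intercept; the slope times
$M/n$ estimates $h^2$ (clamped to $[0.001, 1]$). We use the standard
two-step heteroskedasticity weighting, $w_j = 1/\big(\ell_j (1 + n h^2
\ell_j/M)^2\big)$, iterated three times from an unweighted initial slope.
At desk scale (thousands of variants rather than a million) the unweighted
slope is unusably noisy — in our replicates its interquartile range on a
true $h^2 = 0.5$ exceeded 0.3, versus roughly 0.06 weighted — so the
weighted variant is the default and only implementation. A degenerate
design (all $\ell_j$ equal) falls back to the mean-chi-square estimator and
is flagged in the metadata.

## Synthetic data: what it emulates and what it does not

* **LD panel.** Blocks with AR(1) correlation $\rho^{|i-j|}$; by default
  each block draws its own $\rho \in [0.2, 0.9]$, giving the across-genome
  spread of LD scores that LD-score regression requires (a single-$\rho$
  panel has nearly constant $\ell_j$ and makes the regression ill-posed).
  AR(1) blocks are always positive definite, so the Cholesky-based samplers
  never meet a degenerate matrix. MAFs are uniform on $[0.05, 0.5]$.
* **Architectures.** Causal sets are coupled across traits through a shared
  per-variant uniform (nested sets); effects at shared causals are jointly
  Gaussian with the correlation adjusted so the *genetic* correlation
  matches the requested `rg` given the causal overlap. Effects are rescaled
  so $\beta^\top R \beta$ equals the target $h^2$ exactly per realization.
* **Summary statistics.** The default "direct" mode draws
  $\hat\beta = R\beta + e$, $e \sim MVN(0, R/n)$ per block — the exact
  sampling distribution of marginal least-squares effects — and reports
  them on the allele-count scale ($\beta/sd_j$, $se = 1/(\sqrt{n} sd_j)$,
  $sd_j = \sqrt{2\,\mathrm{maf}(1-\mathrm{maf})}$), the convention of real
  GWAS files. A slow "cohort" mode simulates an external cohort and runs
  per-variant regressions; the test suite checks the two agree in mean
  chi-square and in their correlation with the LD-smeared truth.
* **Cohorts.** Genotypes by Gaussian-copula thresholding (two latent
  haplotypes per individual, thresholded at the $1-\mathrm{maf}$ quantile),
  which preserves Hardy–Weinberg margins exactly and block LD approximately.
  Binary traits follow the liability-threshold model: liability = genetic
  value + optional covariate effects (including a sex-by-age interaction
  term for exercising the non-linear-covariate claim) + Gaussian residual
  scaled to unit total variance; a case is liability above
  $\Phi^{-1}(1-K)$. Case-cohort ascertainment keeps all cases and subsamples
  controls to a target case fraction $P \geq K$.
* **Not emulated:** realistic allele-frequency and LD spectra, population
  structure, relatedness, imputation error, and any quantitative model of a
  particular cohort's ascertainment. Tests passing here show the machinery
  is correct under its stated model, not that real-data prediction gains
  will match.

## The stacking models

The lasso stack fits, by `glmnet`, an L1-penalized model over
[covariates + standardized scores] with per-feature penalty factors 0 for
covariates and 1 for scores; the penalty level is the minimum-deviance
choice from an internal 10-fold cross-validation on the training data. The
source code listing behind the published analysis says `alpha = 0` (ridge in
that package), yet the analysis is described as lasso throughout and reports
sparse nonzero-weight counts, which only L1 produces; this package defaults
to `alpha = 1` and exposes the mixing parameter. The boosted model uses
`eta = 0.01`, `nrounds = 10` and logistic or squared-error objectives as
published; these defaults are configuration-exposed and are deliberately
weak learners (ten shallow-shrinkage rounds barely move the predictions —
visible in every comparison this package computes).

The mixed model boosts the covariates alone in stage 1 and feeds that risk
score, unpenalized, into the lasso over scores in stage 2. The stage-1
predictions entering stage 2 are cross-fitted (5-fold out-of-fold): feeding
in-sample boosted predictions lets the unpenalized stage-1 feature absorb
overfit signal and measurably degrades out-of-sample accuracy. The model
kept for prediction time is refitted on all training rows.

`simplify_stack` keeps scores with $|w| > 0.01$ (configurable) and refits;
an empty selection degrades to the covariates-only model, flagged.

## Evaluation and the liability scale

Out-of-sample discipline: per fold, the library is restandardized on the
training individuals only (the leakage-safe default; whole-sample
standardization is available by `leakage_safe = FALSE`), models including
the penalty search are fitted on the training fold, and the pooled test-fold
predictions feed every statistic. Observed-scale $R^2$ is the squared
correlation from a linear regression of the (possibly binary) outcome on
the predictor, as the liability conversion requires, even for models trained
by logistic loss. The adjustment for covariates is
$R^2_{adj} = (R^2_{full} - R^2_{cov}) / (1 - R^2_{cov})$. The liability
conversion uses the ascertainment-corrected transformation with prevalence
$K$ and sample case proportion $P$; we transform $R^2_{full}$ and
$R^2_{cov}$ separately and then adjust (the composition order is not fixed
by the published captions; the alternative is available by computing the
adjustment first). Quintile odds ratios come from a logistic regression on
quintile indicators (reference: middle quintile) plus covariates, with
quintile boundaries on pooled out-of-sample scores and ties broken by
stable rank. Confidence intervals are percentile bootstraps over
individuals (10,000 replicates at full scale; the bundled demo uses 2,000
to keep a complete run under a minute per model on one CPU). No
multiple-testing adjustment is applied across outcomes; intervals are
reported as-is.

## Benchmarks

The selection-index benchmark weights standardized scores using only
summary-level genetic parameters: expected own-trait accuracy
$r_i^2 = h_i^2/(1 + M_e/(n_i h_i^2))$, index covariances $V_{ii} = 1$,
$V_{ij} = r_g(i,j)\, r_i r_j$, target covariances
$c_i = r_g(i,T)\, r_i \sqrt{h_T^2}$, weights $w = V^{-1}c$ (pseudo-inverse
with a flag when singular). $M_e$, the effective number of independent
markers, defaults to 60,000 at genome scale; the demo pipeline derives it
from the panel as $m / \bar\ell$. All intermediates ($r_i^2$, $V$, $c$) are
returned for audit. The BLUP benchmark is exact ridge regression on
standardized dosages with $\lambda = M(1-h^2)/(nh^2)$, solved in the dual
($n \times n$) form when $n < M$, with out-of-fold scores; it stands in for
an infinitesimal-model mixed-model predictor and is labelled as such.

## The bundled desk-scale study

The demo configuration (`inst/extdata/demo_config.yaml`) fixes the study
conditions: 2,000 variants in 40 heterogeneous AR(1) blocks; 20 traits with
$h^2 = 0.5$ and polygenicity 0.05, the target correlated 0.5 with every
auxiliary and auxiliaries 0.3 with each other; a target GWAS of n = 1,000
against auxiliary GWAS of n = 50,000 (the "target underpowered, correlated
auxiliaries well-powered" regime the framework is for — with a few thousand
variants a target GWAS of n = 5,000 would already saturate the single PGS
and leave nothing to improve); a cohort of 4,000 individuals with binary
prevalence K = 0.2, sex and age covariates with small liability effects and
20 noise PCs. The hyperparameter-recovery experiment uses polygenicity 0.2:
with only ~100 causals spread over 40 blocks, causal-placement noise alone
dominates any chi-square regression at this panel size. One full pipeline
run takes roughly 40 seconds on a single CPU.

## Degenerate inputs and numerical edges

* Strand-ambiguous (A/T, C/G) variants are dropped at harmonization;
  duplicate record ids keep the smallest-se copy; missing frequency falls
  back to panel MAF within SD-QC.
* A file can fail at any stage (unparseable, no overlap, gate, no converged
  chains) — the library build logs a reason code and continues; an empty
  library is the only fatal outcome.
* Near-constant score columns (sd below $10^{-8}$) are dropped with a log
  entry; a constant stage-1 risk reduces the mixed model to a scores-only
  lasso, flagged.
* Perfect separation in the covariate GLM falls back to a tiny-ridge fit,
  flagged. Degenerate quintile cells yield infinite log-ORs with undefined
  CIs, flagged per cell.
* All randomness flows from one master seed through fixed per-operation
  offsets (recorded in metadata); reruns of the whole pipeline into a fresh
  directory reproduce byte-identical artifacts, which the test suite checks
  with md5 checksums.

## Known limitations

* The AR(1)-block world is much easier than real LD; prediction accuracies
  here say nothing quantitative about real cohorts.
* The case-oversampling knob is a generic stand-in for case-cohort designs,
  not a calibration to any particular register cohort.
* The selection-index benchmark here uses simulation-true genetic
  parameters (an oracle, i.e. the benchmark is flattered); plug-in
  estimates via `ldsc_h2` and the cross-trait LD-score slope (`ldsc_rg`)
  are provided but are thin estimators.
* Sample overlap between library GWAS and the evaluation cohort is not
  screened automatically; the simulator never produces it, and an
  automated bivariate-intercept check is future work.
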