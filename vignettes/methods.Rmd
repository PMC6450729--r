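---
title: "Methods: phenome-wide causal screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide causal screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## Scope and model

`mrscreen` implements the statistical machinery of a phenome-wide causal
screen against a disease outcome such as amyotrophic lateral sclerosis
(ALS): two-sample Mendelian randomization (MR) with a full sensitivity
battery, LD score regression (LDSC) genetic correlation, Bayesian
colocalization, and weighted genetic risk scoring — plus a synthetic-data
module that generates every input with recorded ground truth.

Two-sample MR treats genetic variants as instruments. For variant $j$ with
exposure effect $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) and outcome effect
$\hat\beta_{Yj}$ (SE $\sigma_{Yj}$), the Wald ratio is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order SE
$\sigma_{Yj}/|\hat\beta_{Xj}|$. The IVW estimate pools the ratios with
weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ — equivalently a weighted
regression of outcome on exposure effects constrained through the origin.
MR-Egger frees the intercept (its distance from zero measures directional
pleiotropy); the weighted median takes the weight-0.5 quantile of the
ratios and is consistent while less than half the weight is invalid.

## Conventions and numerical choices

These follow the dominant practice in two-sample MR software; each is a
point where the underlying study is silent, so the package documents its
own choice:

* **Random-effects IVW by default.** The fixed-effect SE is inflated by
  $\max(1, \sqrt{Q/(k-1)})$ (multiplicative random effects, residual scale
  floored at 1). A `model = "fixed"` switch disables it. IVW p-values use
  the normal reference; Egger uses $t_{k-2}$, and Egger inputs are first
  re-oriented so all exposure effects are non-negative.
* **Wald SE.** First-order delta method by default; the second-order form
  (adding exposure sampling variance) sits behind `second_order = TRUE`.
* **Weighted-median SE** comes from a seeded parametric bootstrap
  (defaults: 1000 draws); the seed is recorded in every result row so any
  output is reproducible.
* **Palindromic variants** (A/T, C/G) are frequency-resolved: orientation
  is accepted only when both allele frequencies lie outside
  [0.42, 0.58]; otherwise the variant is dropped and counted. The band is
  the common two-sample MR convention for discarding near-0.5 palindromes;
  `palindrome_action = "drop"` removes all palindromes instead.
* **Clumping** is greedy by ascending p-value (ties broken by variant id,
  which makes the output invariant to input order) with an intra-chromosomal
  ±10 Mb window at r² < 0.001. Variants missing from the LD panel are kept
  with a warning by default — dropping data silently would make synthetic
  tests and real screens hard to audit — with a strict mode available.
* **Proxy substitution** (best r² ≥ 0.8) is off by default because it
  requires an LD panel covering the outcome; when used, the exposure effect
  is re-signed by the sign of the LD correlation.
* **Steiger directionality** uses the observed-scale approximation
  $r^2_j = z_j^2/(z_j^2+n-2)$ summed per study, comparing
  Fisher-transformed $\sqrt{r^2}$ at the effective sample size
  $\min(n_X, n_Y)$. Liability-scale correction for binary traits is out of
  scope and documented as such.
* **Multi-allelic records are rejected** at read time (exactly two alleles
  per record); the source study does not state its handling.
* **LDSC** regresses $\chi^2$ on LD scores with a free intercept, weights
  $1/(\ell (1 + n h^2 \ell/M)^2)$ iterated twice from an unweighted fit,
  and 200 contiguous delete-one-block jackknife blocks. The genetic
  covariance regression is weighted by the geometric mean of the two
  univariate weight functions — a deliberate choice that makes
  `rg(trait, itself) = 1` hold exactly rather than only approximately.
  Only observed-scale heritability is reported, and there is no
  constrained-intercept mode. Traits with $\hat h^2 \le 0$ get an
  undefined rg with a reason code, mirroring how trait libraries mark
  unusable entries; the heritability-bounds filter for the scan defaults
  to $h^2 \in (0, 1]$.
* **Colocalization** uses Wakefield log approximate Bayes factors
  ($\log ABF = \tfrac12\log(1-r) + \tfrac12 z^2 r$, $r = W/(V+W)$) with
  prior effect SDs 0.20 (binary) / 0.15 (quantitative) and priors
  $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, under the single causal
  variant per locus assumption. All accumulation is log-space with
  log-sum-exp so panels with $z \approx 40$ remain finite; per-region and
  per-variant posteriors are both emitted because published captions are
  often ambiguous about which they quote. PPH4 > 0.95 flags strong
  colocalization.
* **Risk-score weights are configurable**: the screen's convention of
  weighting instruments by their *outcome*-GWAS betas is preserved as the
  stated default even though weighting by exposure betas is more standard —
  the option is exposed rather than silently corrected. Quintile membership
  uses rank-based equal-size groups with ties resolved deterministically by
  sample id; quasi-separation triggers a flagged Firth-penalized refit, and
  aliased covariates (e.g. sex inside a single-sex stratum) are dropped
  before fitting.
* **Multivariable MR** regresses outcome effects on the exposure-effect
  matrix without intercept (weights $1/\sigma_{Yj}^2$), reporting
  conditional instrument-strength F per exposure. Lasso selection uses
  10-fold cross-validation at a recorded fold seed and `lambda.1se`, then
  refits the selection unpenalized.
* **Screen gates.** Phase I keeps IVW p ≤ 0.05; sensitivity additionally
  requires Egger and weighted-median p ≤ 0.05; replication requires a
  sign-concordant sensitivity-passing hit in the other cohort class
  (published vs biobank). Matching is category-level by default — a trait
  with no counterpart in the other cohort class passes the replication gate
  vacuously, which mirrors screens whose final traits come from mixed
  sources; strict pairwise matching is available. No multiplicity
  correction is applied inside the MR phase (replication substitutes for
  it), but BH-adjusted IVW p-values are reported in a side column. The BH
  family for the LDSC scan is all traits with a defined rg; its size is
  recorded in the report.

## What the synthetic generators emulate

`simulate_two_sample()` draws summary statistics directly from their
asymptotic distributions: instruments (one per LD block, effects scaled to
hit the configured exposure variance $h^2_X$, default 0.1 across 50
instruments) affect the exposure; the outcome effect of variant $j$ is
$\theta\,\beta_{Xj} + \alpha_j + \varepsilon_j$ where $\alpha_j$ is the
pleiotropy model (none / balanced / directional with mean $\alpha$). Direct
effects are oriented relative to the exposure-increasing allele — otherwise
directional pleiotropy would cancel under Egger's re-orientation and the
intercept estimand would not equal $\alpha$ — and `pleio_frac` selects
invalid instruments by cumulative IVW-weight share (their exposure-variance
share), so "40% invalid" means 40% of the weight, the quantity the weighted
median's breakdown bound is stated in. The
estimation noise is LD-block-correlated within each study and correlated
*between* studies with correlation `overlap_frac * rho_pheno` to emulate
sample overlap. Allele representations in the outcome are randomly swapped
(30%) or strand-complemented (20%) so harmonization is exercised
end-to-end; allele pairs are non-palindromic by construction, and
palindrome handling is tested on hand-built records instead.
Defaults — 100k samples per study, 30% case fraction, MAF uniform on
[0.05, 0.5], blocks of 10 variants at r = 0.5 — describe a well-powered
modern GWAS pair.

`simulate_ldsc()` draws z-score pairs from the bivariate LDSC model
($E[z_1 z_2] = \sqrt{n_1 n_2}\, \rho_g \ell/M + c$) over fabricated
gamma-tailed LD scores; the cross-intercept $c$ equals
`overlap_frac * rho_pheno`. `simulate_coloc_region()` builds one region
with block LD and a shared, distinct, single-trait or absent causal
architecture. `simulate_grs_cohort()` is the one genotype-level generator:
binomial dosages, a logistic liability in the standardized score, sex, age
and 20 principal components, and subgroup strata.

What these generators do **not** emulate: realistic human LD maps,
population stratification, uneven sample-size columns, liability-scale
case ascertainment, or winner's-curse from discovery-stage selection. A
green test therefore establishes that the estimators are correct and
calibrated *under their stated models*, not that any particular real-data
estimate is right.

Every generator is a pure function of its configuration; sub-stream seeds
are derived deterministically per component, so adding one simulation stage
never perturbs another's draws.

## Worked example

```{r example}
sim <- simulate_two_sample(sim_config(seed = 7, theta = 0.2))
sel <- select_instruments(sim$exposure)           # p < 5e-8, >= 2 SNPs
ins <- suppressWarnings(clump(sel$instruments, sim$ld))
shared <- intersect(ins$variant_id, sim$outcome$data$variant_id)
h <- harmonize(ins[ins$variant_id %in% shared, ],
               sim$outcome$data[sim$outcome$data$variant_id %in% shared, ],
               n_exp = 1e5, n_out = 1e5)
bat <- mr_battery(h, n_boot = 500, seed = 7)
bat$ivw
bat$egger_intercept
bat$steiger$direction_ok
```

## Known limitations

* Fixed- vs random-effects IVW cannot be adjudicated against published
  tables without the underlying instrument data; both are implemented and
  the default documented.
* The conditional F reported by the multivariable module is a plain
  weighted-residual statistic, not the covariance-corrected version; it is
  a screening diagnostic only.
* Reverse-direction MR reuses the forward battery with roles swapped; its
  interpretation (a null reverse estimate supports forward causality) is a
  heuristic, not a test with controlled error rates.
* The acceptance suite's replicate counts are sized for a single CPU;
  bootstrap draws are reduced to 300 where only an SE is needed, which
  leaves coverage estimates unchanged to well within the asserted margins.
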