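---
title: "Twin-based heritability, genetic correlation, and latent brain-behavior analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-based heritability, genetic correlation, and latent brain-behavior analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinherit)
```

## What the package models

`twinherit` implements the analysis chain used to ask whether behavioral
phenotypes (sleep duration, sleep quality, BMI, IQ, depression) and
parcel-wise cortical thickness share familial and neuroanatomical
structure in an extended-twin cohort:

1. **Univariate polygenic model.** A trait $y$ is modelled as
   $y \sim N(X\beta,\; \sigma_p^2\,(h^2 K + (1-h^2) I))$, where $K$ is the
   expected additive-genetic relatedness (1 for MZ co-twins, 0.5 for DZ
   co-twins and full siblings, 0 otherwise) and $h^2$ is the fraction of
   the phenotypic variance (after fixed effects) attributable to additive
   genetic variance. Phenotypes that covary more strongly between
   genetically closer relatives get higher $h^2$.
2. **Bivariate polygenic model.** Two traits are fitted jointly with 2x2
   genetic and environmental covariance components
   ($G \otimes K + E \otimes I$), giving the genetic correlation $\rho_g$
   (pleiotropy), the environmental correlation $\rho_e$, and the implied
   phenotypic correlation
   $\rho_p = \rho_g\sqrt{h_1^2 h_2^2} + \rho_e\sqrt{(1-h_1^2)(1-h_2^2)}$.
3. **Covariate-adjusted association mapping.** Spearman correlations of
   residualized variables per cortical parcel, with BH false-discovery
   control across the parcel family and percentile-bootstrap confidence
   intervals; `map_similarity()` compares the spatial pattern of two
   parcel maps across samples.
4. **PLS correlation.** SVD of the brain-behavior cross-covariance of
   residualized, z-scored matrices; permutation inference on the singular
   values; bootstrap ratios for salience stability; network-level
   summaries; out-of-sample projection of saliences.

A synthetic-cohort generator closes the loop: it draws pedigrees and
phenotypes from exactly the generative model the estimators assume, so
every stage can be verified by parameter recovery.

## Why pedigree-expected relatedness

Empirical genotype-derived kinship (as computed by tools like KING) cannot
be distributed with a package, and for MZ/DZ/sibling designs the expected
kinship coefficients are the classical, analytically verifiable choice.
The package therefore builds $K$ from pedigree labels alone: MZ co-twins
1, DZ co-twins and labelled siblings 0.5, everything else 0. Co-familial
individuals *not* in a shared MZ/DZ/SIB group get relatedness 0, matching
cohorts assembled from twin pairs plus unrelated singletons; half-siblings
and multi-generation links are out of scope. Degenerate pair groups of
size one are demoted to singletons with a warning rather than rejected,
because real pedigree tables routinely lose a co-twin to QC.

## Numerical design of the likelihood machinery

$K$ is block-diagonal by family, so the log-likelihood factorizes over
family blocks. Each block pattern (MZ pair, DZ pair, sibship, singleton)
is eigendecomposed once and cached; in the eigenbasis the covariance is
diagonal (univariate) or 2x2-blockwise (bivariate), making every
likelihood evaluation O(n).

* **Univariate fit.** At fixed $h^2$, $\beta$ and $\sigma_p^2$ have
  closed-form GLS solutions, leaving a one-dimensional profile likelihood
  over $h^2 \in [0, 1)$. The optimizer scans a 26-point grid, then refines
  by bounded scalar minimization around the grid optimum *and* inside both
  boundary intervals — profiles in small or noisy cohorts can be flat or
  hide narrow boundary optima (e.g. nearly identical MZ co-twin values
  push $h^2 \to 1$, where the covariance degenerates; the optimizer caps
  at $1 - 10^{-6}$ to keep the likelihood finite). Agreement with an
  exhaustive 0.001-step grid search is part of the test suite.
* **Boundary test.** $h^2 = 0$ lies on the boundary of the parameter
  space, so the LRT statistic is referred to a 50:50 mixture of a point
  mass at zero and $\chi^2_1$: $p = \tfrac12 P(\chi^2_1 \ge T)$, $p = 0.5$
  at $T = 0$. Calibration (rejection rate 3–7% at $\alpha = 0.05$ under
  the null) is asserted over 1000 simulated cohorts.
* **Bivariate parameterization.** $G$ and $E$ are parameterized as
  (log-variance, log-variance, atanh-correlation). This guarantees both
  components stay positive semi-definite — the same guarantee a Cholesky
  factorization would give — while making the restricted models for the
  $\rho_g = 0$ and $\rho_e = 0$ likelihood-ratio tests a single fixed
  coordinate, and giving delta-method standard errors for the correlations
  directly from the numerical Hessian. Both traits are standardized
  internally (results are exactly invariant to affine rescaling; the
  reported $G$, $E$ and log-likelihood are mapped back to the input
  scale). The optimizer is L-BFGS-B with box bounds
  ($|\mathrm{atanh}\,\rho| \le \mathrm{atanh}(1-10^{-6})$), started once
  from univariate fits plus the residual phenotypic correlation and four
  seeded random jitters of that point.
* **Standard errors.** Curvature-based SEs are unreliable at boundaries,
  so `se_h2` is `NA` within 0.01 of 0 or 1, and correlation SEs are `NA`
  within 0.01 of $\pm 1$.
* **Interior vs boundary null.** The $\rho_g$/$\rho_e$ tests use plain
  $\chi^2_1$: correlations are interior parameters, unlike variance
  fractions.
* **Convergence defaults.** Profile refinement tolerance $10^{-9}$ on
  $h^2$; L-BFGS-B run with up to 300 iterations per start.

$\rho_e$ is estimated and reported but carries the metadata note that the
environmental component absorbs measurement error; it should not be
over-interpreted.

## Preprocessing choices

* **Inverse normal transform.** Rank-based with the Blom plotting position
  $(r - 3/8)/(n + 1/4)$ and average ranks for ties — the common default in
  variance-components software; the offset is a parameter. By default only
  thickness parcels are transformed before polygenic fits
  (`analysis_config(inverse_normal = )`); behavioral traits can be passed
  through `inverse_normal_transform()` explicitly when desired. This
  asymmetry reflects that parcel summaries are the variables whose
  normality the likelihood leans on hardest.
* **Covariate scheme.** Intercept, age, sex, age x sex, age^2,
  age^2 x sex, plus optional extras (global thickness for whole-brain
  analyses; depression/BMI/IQ for sensitivity runs). Age is deliberately
  not pre-centered: the polynomial span is invariant to affine re-coding
  of age, and that invariance is asserted numerically in the tests rather
  than enforced by centering.
* **Trimmed mean.** Parcel summaries use the 10%-per-tail trimmed mean
  ($k = \lfloor 0.1 n \rfloor$ observations dropped per tail), robust to
  segmentation outliers.
* **Missingness.** Listwise deletion per analysis (trait + covariates +
  pedigree intersection), so each fit reports its own `n_used`.

## Association mapping choices

"Partial Spearman" is residualize-then-rank: both variables are
residualized on the covariate design, then ranked and Pearson-correlated —
the convention of robust-correlation toolboxes that correlate adjusted
variables. With no covariates the estimator is invariant to any strictly
monotone transform; with covariates, invariance holds for affine
transforms only (asserted numerically). p-values use the t-approximation
on the rank correlation; confidence intervals are seeded percentile
bootstraps over individuals (1000 resamples by default; bias-corrected
variants are out of scope). FDR families are one family per analysis —
e.g. 200 parcels for one sleep index in one sample — never pooled across
samples. Subgroup analyses (age strata, short-to-normal vs normal-to-long
sleepers) are row filters applied before `parcelwise_association()`, not
separate code paths.

## PLS choices

* Components: $k$ equals the number of behavior traits (five in the
  motivating analyses).
* Sign convention: each behavior salience is flipped so its
  largest-magnitude entry is positive (the paired brain salience flips
  with it), making output deterministic across SVD implementations.
* Permutation test: the $i$-th permuted singular value is compared with
  the $i$-th observed one, with no Procrustes re-alignment inside the
  permutation loop — the common practice for PLS-correlation significance.
  $p_i = (1 + \#\{s^{perm}_i \ge s_i\})/(n_{perm}+1)$, so the smallest
  attainable p-value is $1/(n_{perm}+1)$.
* Bootstrap: resamples are Procrustes-rotated onto the original behavior
  saliences (with a per-component sign fix so aligned columns have
  nonnegative inner product with the original); BSR = original salience /
  bootstrap SE. A minimum of 50 resamples is enforced; below that the SE
  denominator is too noisy to interpret. Zero-SE parcels get infinite BSR
  flags and are excluded from thresholded summaries.
* Resampling ignores family structure by default, appropriate for
  discovery samples of unrelated individuals; family-aware resampling for
  twin cohorts can be added by permuting whole families, and in-sample
  genetic questions are instead answered by projecting scores and fitting
  the polygenic model on them (see the integration test).
* Network summaries divide suprathreshold counts by network size before
  renormalizing across networks, so large networks do not dominate.

## The synthetic cohort

The generator's defaults are the study conditions used throughout testing:
143 MZ pairs, 85 DZ pairs, 650 singletons (n = 1106), ages uniform on
22–37 with twins sharing age and MZ co-twins sharing sex, and a five-trait
panel (sleep duration, PSQI total, BMI, IQ, depression) with
heritabilities 0.24, 0.12, 0.68, 0.66, 0.24 and means/variances typical of
a young-adult cohort. The cohort-size counts treat reported twin numbers
as individuals (143 and 85 pairs); this is configurable. Covariate effect
defaults (0.1 SD per SD of age, 0.1 SD for sex, 0.05 SD interaction) are
modest, realistic magnitudes chosen once; the estimators absorb them as
fixed effects, so they exercise rather than bias the fits.

Genetic draws use the exact twin-design construction — MZ co-twins share
their standardized genetic score; DZ co-twins get a shared and an
individual part in equal variance — crossed with the matrix square root of
the cross-trait genetic correlation, so the target covariance
$h^2\sigma^2 (K \otimes \rho_g)$ holds exactly in distribution, family by
family, without any global factorization. No shared-household component is
simulated: for extended-twin cohorts of this kind a genes+environment
model is the more parsimonious choice, and adding a household component
would change what $h^2$ means in the recovery tests.

Parcel data are iid Gaussian noise plus planted rank-one components
(`strength * score * loading'`); a planted score can be made heritable by
mixing in a fully genetic standardized score with weight
$\sqrt{\text{score\_h2}}$. What the generator does **not** emulate:
spatial autocorrelation between parcels, realistic cortical geometry,
lifespan age-curves of thickness, non-Gaussian phenotype distributions, or
genotype-level variation. Passing recovery tests therefore demonstrates
the estimators are correct under their assumed model — not that those
assumptions hold in any particular real cohort.

## Problem sizes used in the tests

Unit tests run on cohorts of a few hundred individuals; the statistical
acceptance checks use 100 random small-cohort likelihood comparisons
(n <= 30), 20 grid-search comparisons at n = 12, 1000 null replicates of
100 MZ + 100 DZ pairs for LRT calibration, 50 replicates at the full
n = 1106 default pedigree per recovery setting, and PLS recovery at
n = 500 with 200 parcels, 1000 permutations and 200 bootstraps. These
sizes keep the full suite at a few minutes on one CPU while leaving
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* No dominance, household, X-linked, or longitudinal variance components;
  no genotype-based (SNP) heritability.
* Extended pedigrees beyond MZ/DZ/sibling groups are not modelled.
* Environmental correlations include measurement error by construction.
* PLS inference assumes exchangeable individuals under the default
  resampling; family-structured samples need the projection route.
* The bivariate optimizer can in principle stop at a local optimum;
  multi-start with an informed start makes this rare but not impossible,
  and non-convergence from every start raises an error rather than a
  silent result.
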